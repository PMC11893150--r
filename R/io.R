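# PLINK-2-style phenotype / covariate table readers.
#
# Whitespace- or tab-delimited text with a header line; the header may start
# with #FID/#IID. FID columns are accepted and ignored; IID is required.

read_pheno_table <- function(path, what) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          comment.char = "", na.strings = c("NA", "na"))
  names(df) <- sub("^#", "", names(df))
  if (!"IID" %in% names(df)) {
    abort(sprintf("%s file %s has no IID column", what, path),
          class = "spgwas_format_error")
  }
  df$IID <- as.character(df$IID)
  as_tibble(df[setdiff(names(df), "FID")])
}

#' Read a phenotype table
#'
#' @param path Whitespace/tab-delimited file with a header; columns
#'   `[#FID] [#]IID <phenotype>...`; `NA` marks missing values.
#' @return Tibble with `IID` plus the phenotype columns.
#' @export
read_pheno <- function(path) read_pheno_table(path, "phenotype")

#' Read a covariate table
#'
#' @param path Whitespace/tab-delimited file with a header; columns
#'   `[#FID] [#]IID <covariate>...`.
#' @return Tibble with `IID` plus the covariate columns.
#' @export
read_covar <- function(path) read_pheno_table(path, "covariate")

#' Detect whether a phenotype column is case-control
#'
#' Values confined to \{0, 1, NA\} or PLINK-style \{1, 2, NA\} are treated
#' as binary; the 1/2 coding is recoded to 0/1.
#'
#' @param y Numeric phenotype vector.
#' @return List with `binary` (flag), `y` (recoded when 1/2), `coding`
#'   (`"0/1"`, `"1/2"`, or `NA` for quantitative).
#' @export
detect_binary <- function(y) {
  y <- as.numeric(y)
  vals <- sort(unique(y[!is.na(y)]))
  if (length(vals) == 2L && identical(vals, c(0, 1))) {
    return(list(binary = TRUE, y = y, coding = "0/1"))
  }
  if (length(vals) == 2L && identical(vals, c(1, 2))) {
    return(list(binary = TRUE, y = y - 1, coding = "1/2"))
  }
  list(binary = FALSE, y = y, coding = NA_character_)
}
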