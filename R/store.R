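# On-disk genotype store (.spg).
#
# Layout, little-endian throughout:
#   magic "SPG1" (4 bytes)
#   n_samples  uint32
#   n_variants uint32
#   index: n_variants entries of 4 bytes each
#          (1 byte record_type, 3 bytes record_length)
#   record bodies, back to back, at offsets given by the cumulative sum of
#          record lengths after the index block.
#
# Sidecars (written next to the .spg, PLINK-2-style):
#   <prefix>.pvar  TSV, columns #CHROM POS ID REF ALT (biallelic only)
#   <prefix>.psam  TSV, column #IID

STORE_MAGIC <- charToRaw("SPG1")

uint32_le <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
           (x %/% 16777216) %% 256))
}

read_uint_le <- function(bytes) {
  sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))
}

store_prefix <- function(path) sub("\\.spg$", "", path)

default_variants <- function(m) {
  tibble(
    CHROM = rep("1", m),
    POS = seq_len(max(m, 0L)),
    ID = if (m > 0) sprintf("var%d", seq_len(m)) else character(0),
    REF = rep("A", m),
    ALT = rep("C", m)
  )
}

#' Write a genotype store to disk
#'
#' Serializes a list of encoded records plus sample and variant metadata to
#' an `.spg` file with `.pvar` / `.psam` sidecars.
#'
#' @param records List of records as returned by [choose_encoding()]:
#'   each a list with `record_type` and raw `body`.
#' @param n_samples Number of samples every record covers.
#' @param path Output path; `.spg` is appended if absent.
#' @param variants Optional tibble with columns CHROM, POS, ID, REF, ALT
#'   (one row per record). A minimal table is synthesized if omitted.
#' @param sample_ids Optional character vector of sample IDs; defaults to
#'   `S000001`, ...
#' @return The opened store (see [read_store()]), invisibly.
#' @export
write_store <- function(records, n_samples, path,
                        variants = NULL, sample_ids = NULL) {
  if (!grepl("\\.spg$", path)) path <- paste0(path, ".spg")
  m <- length(records)
  n_samples <- as.integer(n_samples)
  if (is.null(variants)) variants <- default_variants(m)
  if (nrow(variants) != m) {
    abort("variant table must have one row per record")
  }
  if (is.null(sample_ids)) sample_ids <- sprintf("S%06d", seq_len(n_samples))
  if (length(sample_ids) != n_samples) {
    abort("sample_ids must have length n_samples")
  }
  types <- vapply(records, function(r) as.integer(r$record_type), integer(1))
  lens <- vapply(records, function(r) length(r$body), integer(1))
  if (any(lens >= 2^24)) abort("record body exceeds 24-bit length field")
  index <- as.raw(rbind(types,
                        lens %% 256L,
                        (lens %/% 256L) %% 256L,
                        (lens %/% 65536L) %% 256L))
  con <- file(path, "wb")
  ok <- FALSE
  on.exit(if (!ok) close(con))
  writeBin(STORE_MAGIC, con)
  writeBin(uint32_le(n_samples), con)
  writeBin(uint32_le(m), con)
  if (m > 0) writeBin(index, con)
  for (r in records) writeBin(r$body, con)
  close(con)
  ok <- TRUE
  prefix <- store_prefix(path)
  write_pvar(variants, paste0(prefix, ".pvar"))
  write_psam(sample_ids, paste0(prefix, ".psam"))
  invisible(read_store(path))
}

write_pvar <- function(variants, path) {
  hdr <- "#CHROM\tPOS\tID\tREF\tALT"
  rows <- sprintf("%s\t%s\t%s\t%s\t%s", variants$CHROM, variants$POS,
                  variants$ID, variants$REF, variants$ALT)
  writeLines(c(hdr, rows), path)
}

write_psam <- function(sample_ids, path) {
  writeLines(c("#IID", sample_ids), path)
}

read_pvar <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  names(df)[1] <- sub("^#", "", names(df)[1])
  df$POS <- as.integer(df$POS)
  as_tibble(df)
}

read_psam <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character", comment.char = "")
  names(df) <- sub("^#", "", names(df))
  if (!"IID" %in% names(df)) abort_corrupt(".psam is missing the IID column")
  df$IID
}

#' Open a genotype store
#'
#' Reads and validates the header, index and record bodies of an `.spg`
#' file, along with its `.pvar` / `.psam` sidecars when present.
#'
#' @param path Path to the `.spg` file.
#' @return An object of class `spg_store` with fields `n_samples`,
#'   `n_variants`, `record_type`, `record_length`, `variants` (tibble) and
#'   `sample_ids`.
#' @export
read_store <- function(path) {
  if (!file.exists(path)) abort_corrupt(paste0("no such store: ", path))
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12L || !identical(bytes[1:4], STORE_MAGIC)) {
    abort_corrupt("bad magic: not an .spg genotype store")
  }
  n_samples <- read_uint_le(bytes[5:8])
  m <- read_uint_le(bytes[9:12])
  index_end <- 12 + 4 * m
  if (length(bytes) < index_end) abort_corrupt("truncated variant index")
  if (m > 0) {
    idx <- matrix(as.integer(bytes[13:index_end]), nrow = 4L)
    record_type <- idx[1L, ]
    record_length <- idx[2L, ] + 256 * idx[3L, ] + 65536 * idx[4L, ]
  } else {
    record_type <- integer(0)
    record_length <- numeric(0)
  }
  offsets <- index_end + cumsum(c(0, head(record_length, -1L)))
  if (length(bytes) != index_end + sum(record_length)) {
    abort_corrupt("store size does not match index record lengths")
  }
  prefix <- store_prefix(path)
  pvar <- paste0(prefix, ".pvar")
  psam <- paste0(prefix, ".psam")
  variants <- if (file.exists(pvar)) read_pvar(pvar) else
    default_variants(as.integer(m))
  sample_ids <- if (file.exists(psam)) read_psam(psam) else
    sprintf("S%06d", seq_len(n_samples))
  if (length(sample_ids) != n_samples) {
    abort_corrupt(".psam sample count disagrees with store header")
  }
  structure(
    list(path = path, n_samples = as.integer(n_samples),
         n_variants = as.integer(m), record_type = record_type,
         record_length = record_length, offset = offsets,
         bytes = bytes, variants = variants, sample_ids = sample_ids),
    class = "spg_store"
  )
}

#' @exportS3Method base::print
print.spg_store <- function(x, ...) {
  cat("<spg genotype store> ", x$n_variants, " variants x ", x$n_samples,
      " samples (", sum(x$record_type == RECORD_SPARSE),
      " sparse records)\n", sep = "")
  invisible(x)
}

store_body <- function(store, j) {
  len <- store$record_length[j]
  if (len == 0) return(raw(0))
  store$bytes[seq.int(store$offset[j] + 1, length.out = len)]
}

#' Densify one variant of a store
#'
#' @param store An `spg_store`.
#' @param j Variant index (1-based, store order).
#' @return Integer vector of genotype codes, length `n_samples`.
#' @export
get_variant <- function(store, j) {
  decode_variant(store$record_type[j], store_body(store, j), store$n_samples)
}

#' Stream a sparse record without densifying
#'
#' Returns the difflist entries of a sparse-encoded variant in O(k) work,
#' never allocating an n-length array. Dense records signal a classed
#' `spgwas_not_sparse` condition so callers can fall back to
#' [decode_variant()].
#'
#' @inheritParams get_variant
#' @return An `spg_sparse_record`: 1-based `sample` indices, `code`
#'   (values 1/2/3), `k`, `n_samples`.
#' @export
iter_sparse <- function(store, j) {
  if (store$record_type[j] != RECORD_SPARSE) abort_not_sparse()
  ent <- decode_sparse_entries(store_body(store, j), store$n_samples)
  new_sparse_record(ent$sample, ent$code, store$n_samples)
}

# Either representation as entries; used by engines that work in O(k) when
# they can and O(n) when they must.
variant_entries <- function(store, j) {
  if (store$record_type[j] == RECORD_SPARSE) {
    iter_sparse(store, j)
  } else {
    codes <- get_variant(store, j)
    nz <- which(codes != 0L)
    new_sparse_record(nz, codes[nz], store$n_samples)
  }
}

#' Build a store from a dense genotype matrix
#'
#' Encodes each column with [choose_encoding()] and writes a complete store.
#' Mainly useful for tests and small examples; real data arrives through
#' [import_vcf()] or [simulate_store()].
#'
#' @param G Integer matrix, samples x variants, codes in `{0,1,2,3}`.
#' @inheritParams write_store
#' @return The opened `spg_store`, invisibly.
#' @export
store_from_matrix <- function(G, path, variants = NULL, sample_ids = NULL) {
  records <- lapply(seq_len(ncol(G)), function(j) choose_encoding(G[, j]))
  write_store(records, nrow(G), path, variants = variants,
              sample_ids = sample_ids)
}

# Map a diploid GT string to a genotype code. Anything that is not two
# non-missing alleles (missing, half-calls, haploid) maps to 3.
gt_to_code <- function(gt) {
  code <- rep(3L, length(gt))
  gt <- sub(":.*$", "", gt)
  known <- !is.na(gt)
  alleles <- strsplit(ifelse(known, gt, "."), "[/|]")
  nalt <- vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    v <- suppressWarnings(as.integer(a))
    if (anyNA(v) || any(v > 1L)) return(NA_integer_)
    sum(v)
  }, integer(1))
  code[!is.na(nalt)] <- nalt[!is.na(nalt)]
  code
}

#' Import hard-call genotypes from a VCF into a store
#'
#' Reads the GT field of a VCF (via the vcfR parser), maps each biallelic
#' record to additive genotype codes (missing and half-calls become code 3),
#' skips multiallelic sites with a warning, and writes an `.spg` store with
#' `.pvar` / `.psam` sidecars.
#'
#' @param vcf_path Path to a VCF (optionally bgzipped).
#' @param out_prefix Output prefix; writes `<out_prefix>.spg/.pvar/.psam`.
#' @return The opened `spg_store`, invisibly.
#' @export
import_vcf <- function(vcf_path, out_prefix) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  m_all <- nrow(fix)
  if (m_all == 0L) {
    return(write_store(list(), n_samples = max(ncol(vcf@gt) - 1L, 0L),
                       path = paste0(out_prefix, ".spg"),
                       variants = default_variants(0L)[0, ],
                       sample_ids = colnames(vcf@gt)[-1]))
  }
  if (ncol(vcf@gt) < 2L) abort("VCF has no sample columns")
  fmt <- vcf@gt[, 1L]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF records lack a GT field", class = "spgwas_format_error")
  }
  biallelic <- !grepl(",", fix[, "ALT"]) & fix[, "ALT"] != "." &
    !is.na(fix[, "ALT"])
  if (any(!biallelic)) {
    warn(sprintf("skipping %d multiallelic/invalid-ALT record(s)",
                 sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  sample_ids <- colnames(gt)
  keep <- which(biallelic)
  records <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    records[[i]] <- choose_encoding(gt_to_code(gt[keep[i], ]))
  }
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    sprintf("%s:%s", fix[keep, "CHROM"], fix[keep, "POS"])[is.na(ids) | ids == "."]
  variants <- tibble(
    CHROM = fix[keep, "CHROM"],
    POS = as.integer(fix[keep, "POS"]),
    ID = ids,
    REF = fix[keep, "REF"],
    ALT = fix[keep, "ALT"]
  )
  write_store(records, length(sample_ids), paste0(out_prefix, ".spg"),
              variants = variants, sample_ids = sample_ids)
}
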