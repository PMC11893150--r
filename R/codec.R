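# Per-variant genotype codecs.
#
# Genotype codes are additive alt-allele counts with a missing sentinel:
#   0 hom-ref, 1 het, 2 hom-alt, 3 missing.
# Two on-disk record types exist:
#   type 0 ("dense"):  ceil(n/4) bytes, 2 bits per sample in sample order,
#                      little-endian bit packing within each byte;
#   type 1 ("sparse"): a difflist -- varint(k), then k delta-encoded LEB128
#                      varints of 0-based sample indices (first absolute,
#                      rest gaps from the previous index), then ceil(k/4)
#                      bytes of 2-bit codes in entry order.
# The difflist stores every sample that deviates from the implicit all-
# hom-ref background: hets, hom-alts AND missing calls, so downstream
# engines can downdate for missingness without densifying.

RECORD_DENSE <- 0L
RECORD_SPARSE <- 1L

validate_codes <- function(codes) {
  if (length(codes) < 1L) {
    abort("genotype vector must contain at least one sample")
  }
  if (anyNA(codes) || any(codes < 0 | codes > 3)) {
    abort("genotype codes must be integers in {0, 1, 2, 3} (3 = missing)")
  }
  as.integer(codes)
}

# LEB128 varint encoder, vectorized over values (doubles are exact far
# beyond the uint32 range needed here).
encode_varints <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0L) return(raw(0))
  nb <- 1L + (v >= 128) + (v >= 128^2) + (v >= 128^3) + (v >= 128^4)
  maxb <- max(nb)
  bytes <- matrix(0L, nrow = maxb, ncol = length(v))
  for (j in seq_len(maxb)) {
    byte_j <- (v %/% 128^(j - 1)) %% 128
    cont <- as.integer(j < nb) * 128L
    bytes[j, ] <- as.integer(byte_j) + cont
  }
  keep <- rep(seq_len(maxb), times = length(v)) <= rep(nb, each = maxb)
  as.raw(bytes[matrix(keep, nrow = maxb)])
}

varint_length <- function(values) {
  v <- as.numeric(values)
  1L + (v >= 128) + (v >= 128^2) + (v >= 128^3) + (v >= 128^4)
}

# Decode the first `count` varints of `body` starting at byte `at`.
# Returns values and the offset one past the last byte consumed.
decode_varints <- function(body, count, at = 1L) {
  if (count == 0L) return(list(values = numeric(0), at = at))
  ints <- as.integer(body)
  n <- length(ints)
  if (at > n) abort_malformed("truncated record body: varint expected past end")
  terminal <- ints[at:n] < 128L
  ends <- which(terminal)
  if (length(ends) < count) {
    abort_malformed("truncated record body: varint stream ends early")
  }
  ends <- ends[seq_len(count)] + (at - 1L)
  starts <- c(at, head(ends, -1L) + 1L)
  widths <- ends - starts + 1L
  if (any(widths > 5L)) {
    abort_malformed("varint overrun: more than 5 bytes in one value")
  }
  pos <- sequence(widths)                       # position within each varint
  id <- rep(seq_len(count), times = widths)
  payload <- ints[sequence(widths, from = starts)] %% 128L
  values <- rowsum(payload * 128^(pos - 1), id)[, 1L]
  list(values = as.numeric(values), at = ends[count] + 1L)
}

# Pack genotype codes (values 0..3) at 2 bits each, little-endian within
# each byte; pad the final byte with zeros.
pack_codes <- function(codes) {
  k <- length(codes)
  if (k == 0L) return(raw(0))
  nb <- ceiling(k / 4)
  padded <- c(as.integer(codes), integer(nb * 4L - k))
  m <- matrix(padded, nrow = 4L)
  as.raw(colSums(m * c(1L, 4L, 16L, 64L)))
}

unpack_codes <- function(bytes, k) {
  if (k == 0L) return(integer(0))
  ints <- as.integer(bytes)
  m <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
             (ints %/% 16L) %% 4L, (ints %/% 64L) %% 4L)
  as.integer(m)[seq_len(k)]
}

#' Encode a genotype vector as a sparse difflist record body
#'
#' Produces the difflist body: a varint entry count, delta-encoded LEB128
#' varints of the 0-based sample indices of all non-hom-ref samples (first
#' index absolute, subsequent as gaps from the previous index), then the
#' 2-bit-packed genotype codes of those entries. A singleton variant among
#' 400 000 samples costs 5 bytes instead of the 100 000 a fixed-width
#' encoding needs.
#'
#' @param codes Integer vector of per-sample genotype codes in `{0,1,2,3}`
#'   (0 hom-ref, 1 het, 2 hom-alt, 3 missing), one per sample.
#' @return A raw vector: the record body.
#' @seealso [encode_dense()], [choose_encoding()], [decode_variant()]
#' @export
#' @examples
#' body <- encode_sparse(c(0L, 0L, 1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L))
#' length(body)
#' decode_variant(1L, body, 10L)
encode_sparse <- function(codes) {
  codes <- validate_codes(codes)
  idx <- which(codes != 0L)
  k <- length(idx)
  if (k == 0L) return(encode_varints(0))
  idx0 <- idx - 1L                               # 0-based on disk
  gaps <- c(idx0[1L], diff(idx0))
  c(encode_varints(k), encode_varints(gaps), pack_codes(codes[idx]))
}

#' Encode a genotype vector as a fixed-width 2-bit record body
#'
#' Packs all `n` genotype codes at 2 bits per sample, in sample order,
#' little-endian within each byte: `ceiling(n/4)` bytes regardless of
#' content.
#'
#' @inheritParams encode_sparse
#' @return A raw vector of `ceiling(length(codes)/4)` bytes.
#' @export
encode_dense <- function(codes) {
  pack_codes(validate_codes(codes))
}

#' Body sizes both codecs would produce, without encoding
#'
#' @inheritParams encode_sparse
#' @return Named numeric vector with elements `sparse` and `dense`, in bytes.
#' @export
encoding_sizes <- function(codes) {
  codes <- validate_codes(codes)
  n <- length(codes)
  idx <- which(codes != 0L)
  k <- length(idx)
  sparse <- if (k == 0L) {
    as.numeric(varint_length(0))
  } else {
    idx0 <- idx - 1L
    gaps <- c(idx0[1L], diff(idx0))
    varint_length(k) + sum(varint_length(gaps)) + ceiling(k / 4)
  }
  c(sparse = sparse, dense = ceiling(n / 4))
}

#' Pick the smaller encoding for a variant
#'
#' Encodes with whichever codec yields the fewer bytes; ties go to the dense
#' encoding (its decoder is branch-free).
#'
#' @inheritParams encode_sparse
#' @return A list with `record_type` (0 dense, 1 sparse) and `body` (raw).
#' @export
choose_encoding <- function(codes) {
  sizes <- encoding_sizes(codes)
  if (sizes[["sparse"]] < sizes[["dense"]]) {
    list(record_type = RECORD_SPARSE, body = encode_sparse(codes))
  } else {
    list(record_type = RECORD_DENSE, body = encode_dense(codes))
  }
}

# Decode a sparse body into (1-based index, code) entries.
decode_sparse_entries <- function(body, n_samples) {
  kx <- decode_varints(body, 1L)
  k <- kx$values
  if (k > n_samples) {
    abort_malformed("sparse record claims more entries than samples")
  }
  gx <- decode_varints(body, k, at = kx$at)
  idx0 <- cumsum(gx$values)
  if (k > 0L && idx0[k] >= n_samples) {
    abort_malformed("sparse record sample index out of range")
  }
  if (k > 1L && any(diff(idx0) <= 0)) {
    abort_malformed("sparse record sample indices not strictly increasing")
  }
  code_bytes <- ceiling(k / 4)
  if (length(body) != gx$at - 1L + code_bytes) {
    abort_malformed("sparse record body length mismatch")
  }
  codes <- unpack_codes(body[seq.int(gx$at, length.out = code_bytes)], k)
  if (any(codes == 0L)) {
    abort_malformed("sparse record contains a hom-ref entry")
  }
  list(sample = as.integer(idx0) + 1L, code = codes, k = as.integer(k))
}

#' Decode a record body back to a dense genotype vector
#'
#' Exact inverse of [encode_sparse()] / [encode_dense()]: expands the record
#' to an array of `n_samples` 2-bit codes.
#'
#' @param record_type Integer, 0 (dense 2-bit) or 1 (sparse difflist).
#' @param body Raw vector produced by the matching encoder.
#' @param n_samples Number of samples the record covers.
#' @return Integer vector of genotype codes, length `n_samples`.
#' @export
decode_variant <- function(record_type, body, n_samples) {
  n_samples <- as.integer(n_samples)
  if (record_type == RECORD_DENSE) {
    if (length(body) != ceiling(n_samples / 4)) {
      abort_malformed("dense record body has wrong length")
    }
    return(unpack_codes(body, n_samples))
  }
  if (record_type != RECORD_SPARSE) {
    abort_malformed(paste0("unknown record type ", record_type))
  }
  ent <- decode_sparse_entries(body, n_samples)
  out <- integer(n_samples)
  out[ent$sample] <- ent$code
  out
}

new_sparse_record <- function(sample, code, n_samples) {
  structure(
    list(sample = as.integer(sample), code = as.integer(code),
         k = length(sample), n_samples = as.integer(n_samples)),
    class = "spg_sparse_record"
  )
}

#' @exportS3Method base::print
print.spg_sparse_record <- function(x, ...) {
  cat("<sparse variant record> k =", x$k, "of", x$n_samples, "samples\n")
  invisible(x)
}
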