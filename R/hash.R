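# 32-bit fragment hashing and folding.
#
# Fragments are keyed by their canonical SMILES; the fingerprint bit of a
# fragment is crc32(utf8 bytes) mod dim. CRC-32 (IEEE, reflected polynomial
# 0xEDB88320) is used because it is deterministic across platforms and fills
# the 2^32 hash space assumed by the birthday-problem collision accounting.
# R has no unsigned 32-bit type, so arithmetic is done on signed integers
# (bitwShiftR is a logical shift) and the result is mapped to [0, 2^32) as a
# double on the way out.

.crc_env <- new.env(parent = emptyenv())

.crc32_table <- function() {
  if (!is.null(.crc_env$table)) return(.crc_env$table)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  tab <- 0:255
  for (k in 1:8) {
    odd <- bitwAnd(tab, 1L) == 1L
    tab <- bitwShiftR(tab, 1L)
    tab[odd] <- bitwXor(tab[odd], poly)
  }
  .crc_env$table <- tab
  tab
}

#' Hash strings to 32-bit integers
#'
#' Deterministic, platform-independent CRC-32 of the UTF-8 bytes of each
#' string, returned as doubles in `[0, 2^32)`. This is the hash used to place
#' fragment SMILES into the fingerprint: the bit index of a fragment is
#' `hash32(smiles) %% dim`.
#'
#' @param x character vector of non-empty strings.
#' @return numeric vector of the same length with values in `[0, 2^32)`.
#' @examples
#' hash32("123456789")  # 3421780262, the classic CRC-32 check value
#' @export
hash32 <- function(x) {
  if (!is.character(x) || length(x) == 0) {
    stop("hash32() expects a non-empty character vector", call. = FALSE)
  }
  if (anyNA(x) || any(!nzchar(x))) {
    stop("hash32() requires non-empty, non-NA strings", call. = FALSE)
  }
  tab <- .crc32_table()
  bytes <- lapply(x, function(s) as.integer(charToRaw(enc2utf8(s))))
  lens <- lengths(bytes)
  maxlen <- max(lens)
  crc <- rep(-1L, length(x))  # init 0xFFFFFFFF
  for (j in seq_len(maxlen)) {
    act <- which(lens >= j)
    b <- vapply(bytes[act], `[[`, integer(1), j)
    idx <- bitwAnd(bitwXor(crc[act], b), 255L) + 1L
    crc[act] <- bitwXor(bitwShiftR(crc[act], 8L), tab[idx])
  }
  crc <- bitwNot(crc)  # final xor 0xFFFFFFFF
  out <- as.numeric(crc)
  out[out < 0] <- out[out < 0] + 2^32
  out
}

#' Fold a 32-bit hash into a fingerprint index
#'
#' @param h numeric vector of hashes in `[0, 2^32)`.
#' @param dim fingerprint length (positive integer).
#' @return integer vector of 0-based bit indices in `[0, dim)`.
#' @export
fold_hash <- function(h, dim) {
  stopifnot(dim >= 1)
  as.integer(h %% dim)
}
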