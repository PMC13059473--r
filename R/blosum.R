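#' The 20-letter amino-acid alphabet, in the conventional BLOSUM order
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.blosum_cache <- new.env(parent = emptyenv())

#' Read a substitution matrix in NCBI text layout
#'
#' Parses the whitespace-separated matrix format used by NCBI tools
#' (comment lines start with `#`, first non-comment line holds the column
#' letters, each following line a row letter and its scores).
#'
#' @param path path to the matrix file; defaults to the pinned BLOSUM50
#'   fixture shipped with the package
#' @return square numeric matrix with letter dimnames
#' @export
read_substitution_matrix <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "BLOSUM50.txt", package = "cmhs")
  }
  if (!file.exists(path)) cmhs_stop(paste0("no such matrix file: ", path),
                                    "cmhs_io_error")
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  cols <- strsplit(trimws(lines[[1L]]), "\\s+")[[1L]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1L]])
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1L])))
  rownames(m) <- vapply(rows, `[[`, "", 1L)
  colnames(m) <- cols
  m
}

#' The pinned BLOSUM50 matrix restricted to the 20 standard amino acids
#' @return 20 x 20 numeric matrix, dimnames in [AA_ALPHABET] order
#' @export
blosum50_matrix <- function() {
  if (is.null(.blosum_cache$m)) {
    full <- read_substitution_matrix()
    .blosum_cache$m <- full[AA_ALPHABET, AA_ALPHABET]
  }
  .blosum_cache$m
}

#' Fingerprint of the BLOSUM50 fixture (stored in model checkpoints)
#' @keywords internal
blosum50_fingerprint <- function() {
  m <- blosum50_matrix()
  sprintf("blosum50/%d/%.0f", sum(m), sum(m * m))
}

#' Encode a sequence as rows of the BLOSUM50 matrix
#'
#' Residue i becomes the BLOSUM50 substitution-score row of its letter;
#' positions beyond the sequence end (up to `target_length`) are all-zero
#' pad rows, so variable-length inputs share a common width-20 encoding.
#'
#' @param seq character scalar over the 20-letter alphabet (case-insensitive)
#' @param target_length padded length, `>= nchar(seq)`
#' @return `target_length` x 20 numeric matrix; columns named by residue
#' @export
blosum50_encode <- function(seq, target_length = nchar(seq)) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (target_length < n) {
    cmhs_stop("target_length shorter than sequence", "cmhs_dimension_error")
  }
  letters <- strsplit(seq, "")[[1L]]
  bad <- which(!letters %in% AA_ALPHABET)
  if (length(bad)) {
    cmhs_stop(sprintf("unknown residue '%s' at position %d",
                      letters[bad[1L]], bad[1L]), "cmhs_encoding_error")
  }
  m <- matrix(0, nrow = target_length, ncol = 20L,
              dimnames = list(NULL, AA_ALPHABET))
  if (n > 0L) m[seq_len(n), ] <- blosum50_matrix()[letters, , drop = FALSE]
  m
}

#' BLOSUM50 similarity of two residues
#' @param a,b single residue letters
#' @export
blosum50_score <- function(a, b) {
  blosum50_matrix()[toupper(a), toupper(b)]
}
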