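#' Sequence record
#'
#' Plain container for one amino-acid sequence with its role in a pMHC pair.
#' Peptides must be 8-12 residues; MHC sequences at most 300 after
#' preprocessing (class I convention: the first 300 residues are kept).
#'
#' @param id record identifier
#' @param sequence uppercase sequence over the 20-letter alphabet
#' @param role "MHC" or "peptide"
#' @return object of class `cmhs_seq`
#' @export
sequence_record <- function(id, sequence, role = c("MHC", "peptide")) {
  role <- match.arg(role)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) cmhs_stop(sprintf("empty sequence for '%s'", id),
                                   "cmhs_parse_error")
  letters <- strsplit(sequence, "")[[1L]]
  bad <- which(!letters %in% AA_ALPHABET)
  if (length(bad)) {
    cmhs_stop(sprintf("record '%s': invalid residue '%s' at position %d",
                      id, letters[bad[1L]], bad[1L]), "cmhs_parse_error")
  }
  n <- nchar(sequence)
  if (role == "peptide" && (n < 8L || n > 12L)) {
    cmhs_stop(sprintf("peptide '%s' has length %d, expected 8-12", id, n),
              "cmhs_validation_error")
  }
  if (role == "MHC" && n > 300L) {
    cmhs_stop(sprintf("MHC '%s' has length %d > 300 after preprocessing",
                      id, n), "cmhs_validation_error")
  }
  structure(list(id = id, sequence = sequence, role = role),
            class = "cmhs_seq")
}

#' @export
print.cmhs_seq <- function(x, ...) {
  cat(sprintf("<%s %s: %d aa>\n", x$role, x$id, nchar(x$sequence)))
  invisible(x)
}

#' Read a FASTA file of amino-acid sequences
#'
#' Sequences are uppercased; `*` and gap characters are rejected. MHC
#' sequences longer than 300 residues are truncated to 300 (the class I
#' preprocessing convention) before validation.
#'
#' @param path FASTA file
#' @param role role assigned to every record ("MHC" or "peptide")
#' @return list of [sequence_record()] objects (empty list for empty file)
#' @export
read_fasta <- function(path, role = c("MHC", "peptide")) {
  role <- match.arg(role)
  if (!file.exists(path)) cmhs_stop(paste0("no such file: ", path),
                                    "cmhs_io_error")
  lines <- readLines(path)
  records <- list(); id <- NULL; seq_parts <- character(); first_line <- 0L
  flush <- function() {
    if (is.null(id)) return()
    s <- paste(seq_parts, collapse = "")
    if (!nzchar(s)) cmhs_stop(sprintf("empty sequence for '%s' (line %d)",
                                      id, first_line), "cmhs_parse_error")
    if (role == "MHC" && nchar(s) > 300L) s <- substr(s, 1L, 300L)
    records[[length(records) + 1L]] <<- sequence_record(id, s, role)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      id <- trimws(sub("^>", "", line))
      if (!nzchar(id)) cmhs_stop(sprintf("malformed FASTA header at line %d",
                                         i), "cmhs_parse_error")
      id <- strsplit(id, "\\s+")[[1L]][[1L]]
      seq_parts <- character(); first_line <- i
    } else {
      if (is.null(id)) cmhs_stop(
        sprintf("sequence data before any header at line %d", i),
        "cmhs_parse_error")
      seq_parts <- c(seq_parts, toupper(line))
    }
  }
  flush()
  records
}

#' Write sequence records to FASTA
#' @param records list of [sequence_record()]s
#' @param path output file
#' @export
write_fasta <- function(records, path) {
  lines <- unlist(lapply(records, function(r) c(paste0(">", r$id),
                                                r$sequence)))
  writeLines(lines %||% character(), path)
  invisible(path)
}

#' Convert IC50 (nM) to normalized binding affinity in [0, 1]
#'
#' The standard log-transform of the immunoinformatics benchmarks:
#' `1 - log(ic50) / log(50000)`, clamped to [0, 1]. Strong binders
#' (low IC50) map near 1, non-binders (IC50 >= 50000 nM) to 0.
#'
#' @param ic50 positive numeric vector, nM
#' @return numeric vector in [0, 1], monotone decreasing in `ic50`
#' @export
normalize_ic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    cmhs_stop("ic50 must be finite and > 0", "cmhs_domain_error")
  }
  pmin(1, pmax(0, 1 - log(ic50) / log(50000)))
}

#' Binder / non-binder label from IC50
#'
#' Strict inequality: exactly 500 nM is a non-binder.
#' @param ic50 positive numeric vector, nM
#' @param threshold binder threshold in nM (default 500)
#' @return integer vector of 0/1
#' @export
binarize <- function(ic50, threshold = 500) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    cmhs_stop("ic50 must be finite and > 0", "cmhs_domain_error")
  }
  as.integer(ic50 < threshold)
}

#' Read an affinity table (CSV: mhc_id, peptide, ic50[, split])
#'
#' Populates the derived `affinity` ([normalize_ic50()]) and `label`
#' ([binarize()]) columns.
#'
#' @param path CSV file with header `mhc_id,peptide,ic50`
#' @return data.frame with columns mhc_id, peptide, ic50, affinity, label
#'   (plus `split` when present in the file)
#' @export
read_affinity_table <- function(path) {
  if (!file.exists(path)) cmhs_stop(paste0("no such file: ", path),
                                    "cmhs_io_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mhc_id", "peptide", "ic50")
  miss <- setdiff(need, names(df))
  if (length(miss)) cmhs_stop(paste0("affinity table missing column(s): ",
                                     paste(miss, collapse = ", ")),
                              "cmhs_parse_error")
  df$ic50 <- as.numeric(df$ic50)
  bad <- which(!is.finite(df$ic50) | df$ic50 <= 0)
  if (length(bad)) {
    cmhs_stop(sprintf("non-positive or unparsable ic50 at row %d", bad[1L]),
              "cmhs_validation_error")
  }
  df$peptide <- toupper(df$peptide)
  df$affinity <- normalize_ic50(df$ic50)
  df$label <- binarize(df$ic50)
  df
}

#' Write an affinity table to CSV
#' @param df data.frame with at least mhc_id, peptide, ic50
#' @param path output CSV path
#' @export
write_affinity_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read Calpha/atom records from a PDB-format file
#'
#' Parses ATOM records (fixed columns: atom name, residue sequence number,
#' x, y, z). Residue numbering in the file is 1-based; the returned table
#' keeps the file numbering in `residue_index`.
#'
#' @param path PDB file
#' @return data.frame (`cmhs_atoms`): residue_index, atom_name, x, y, z
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) cmhs_stop(paste0("no such file: ", path),
                                    "cmhs_io_error")
  lines <- readLines(path)
  atom <- lines[startsWith(lines, "ATOM")]
  if (!length(atom)) cmhs_stop(sprintf("no ATOM records in %s", path),
                               "cmhs_parse_error")
  df <- data.frame(
    residue_index = as.integer(substr(atom, 23, 26)),
    atom_name = trimws(substr(atom, 13, 16)),
    x = as.numeric(substr(atom, 31, 38)),
    y = as.numeric(substr(atom, 39, 46)),
    z = as.numeric(substr(atom, 47, 54)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(df$x) | !is.finite(df$y) | !is.finite(df$z))) {
    cmhs_stop(sprintf("unparsable coordinates in %s", path),
              "cmhs_parse_error")
  }
  class(df) <- c("cmhs_atoms", "data.frame")
  df
}

#' Write an atom table as minimal PDB ATOM records
#' @param atoms data.frame with residue_index, atom_name, x, y, z
#' @param path output file
#' @param resname three-letter residue name to stamp (cosmetic)
#' @export
write_pdb <- function(atoms, path, resname = "ALA") {
  lines <- sprintf(
    "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(atoms)),
    substr(sprintf(" %-3s", atoms$atom_name), 1, 4),
    resname, atoms$residue_index, atoms$x, atoms$y, atoms$z)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a pseudo-sequence position list
#'
#' One 1-based MHC residue index per line (binding-site positions).
#' @param path text file
#' @return sorted integer vector of unique 1-based indices
#' @export
read_pseudo_positions <- function(path) {
  if (!file.exists(path)) cmhs_stop(paste0("no such file: ", path),
                                    "cmhs_io_error")
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  idx <- suppressWarnings(as.integer(lines))
  if (any(is.na(idx)) || any(idx < 1L)) {
    cmhs_stop(sprintf("invalid pseudo position entry in %s", path),
              "cmhs_parse_error")
  }
  sort(unique(idx))
}

#' Write a pseudo-sequence position list
#' @param positions integer vector of 1-based indices
#' @param path output file
#' @export
write_pseudo_positions <- function(positions, path) {
  writeLines(as.character(sort(unique(as.integer(positions)))), path)
  invisible(path)
}
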