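# Aligned amino-acid matrices: FASTA I/O and integer encoding.
# An alignment is a plain character matrix, taxa in rows (rownames = labels),
# aligned columns as sites. Gaps "-"/"." and ambiguity codes X/B/Z/J (also
# "?", "*") are treated as missing data.

#' Read an aligned FASTA file of amino-acid sequences
#'
#' @param path Path to an aligned FASTA file (equal-length sequences).
#' @return Character matrix (taxa x sites) with taxon labels as rownames.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) abort(paste0("No sequences in ", path))
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) {
    abort(paste0("Sequences in ", path, " are not aligned (unequal lengths)."))
  }
  labels <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(labels)) abort("Duplicate sequence labels in alignment.")
  m <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(m) <- labels
  m
}

#' Write an alignment to FASTA
#'
#' @param alignment Character matrix (taxa x sites).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  stopifnot(is.matrix(alignment), !is.null(rownames(alignment)))
  lines <- character(2L * nrow(alignment))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(alignment))
  lines[c(FALSE, TRUE)] <- apply(alignment, 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

# Integer encoding: 1..20 in AA_ALPHABET order, NA for gaps/ambiguities.
encode_alignment <- function(alignment) {
  if (is.integer(alignment)) return(alignment)
  stopifnot(is.matrix(alignment))
  enc <- match(toupper(alignment), AA_ALPHABET)
  bad <- !is.na(alignment) & is.na(enc) &
    !(toupper(alignment) %in% MISSING_RESIDUES)
  if (any(bad)) {
    abort(paste0("Unrecognised residue code(s): ",
                 paste(unique(alignment[bad]), collapse = " ")))
  }
  enc <- matrix(as.integer(enc), nrow(alignment), ncol(alignment))
  rownames(enc) <- rownames(alignment)
  enc
}

# Check that alignment covers the tree's leaves; returns the encoded matrix
# with rows ordered to `labels`. Errors list the missing taxa.
align_to_labels <- function(alignment, labels) {
  enc <- encode_alignment(alignment)
  missing <- setdiff(labels, rownames(enc))
  if (length(missing)) {
    abort(paste0("Alignment is missing taxa: ", paste(missing, collapse = ", ")))
  }
  enc[labels, , drop = FALSE]
}
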