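#' Write a simulated dataset as a plain-text fixture bundle
#'
#' Lays out one directory with everything downstream stages consume:
#' `expression_<stage>.tsv` (orthogroup rows, sample columns),
#' `metadata.tsv` (sample, species, stage, replicate), `traits.tsv`,
#' `tree.nwk`, and optionally one FASTA per orthogroup under `alignments/`.
#'
#' @param sim A `sim_expression` object from [simulate_expression()].
#' @param dir Output directory (created if needed).
#' @param alignments Optional list from [simulate_codon_alignments()].
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir, alignments = NULL) {
  stopifnot(inherits(sim, "sim_expression"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(sim$counts)) {
    write_expression_tsv(sim$counts[[st]],
                         file.path(dir, sprintf("expression_%s.tsv", st)))
  }
  utils::write.table(sim$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$traits, file.path(dir, "traits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(alignments)) {
    adir <- file.path(dir, "alignments")
    dir.create(adir, showWarnings = FALSE)
    for (og in names(alignments)) {
      write_alignment_fasta(alignments[[og]],
                            file.path(adir, paste0(og, ".fasta")))
    }
  }
  invisible(dir)
}

#' Write / read an orthogroup x sample expression matrix as TSV
#'
#' First column `orthogroup` holds row ids; remaining columns are samples.
#'
#' @param m Numeric matrix with row and column names.
#' @param path File path.
#' @return `read_expression_tsv()` returns the numeric matrix.
#' @export
write_expression_tsv <- function(m, path) {
  df <- data.frame(orthogroup = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a codon alignment as FASTA
#'
#' @param aln Named character vector of aligned sequences.
#' @param path File path.
#' @return `read_alignment_fasta()` returns a named character vector.
#' @export
write_alignment_fasta <- function(aln, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(aln), path)
  invisible(path)
}

#' @rdname write_alignment_fasta
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
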