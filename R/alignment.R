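#' Construct a protein alignment
#'
#' A `protein_alignment` is a character matrix of single residues with one
#' row per taxon (unique rownames) and one column per alignment site.
#' Sequences may contain the 20 standard residues, the gap character `-`,
#' and ambiguity codes (treated as missing data by the distance functions).
#'
#' @param seqs Either a character matrix of single residues with rownames,
#'   or a named character vector of equal-length sequence strings.
#' @return A `protein_alignment` object (a classed character matrix).
#' @examples
#' aln <- protein_alignment(c(tax1 = "ACDE", tax2 = "ACDF"))
#' n_sites(aln)
#' @export
protein_alignment <- function(seqs) {
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1) {
      stop("aligned sequences must all have equal length; got lengths ",
           paste(unique(lens), collapse = ", "))
    }
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (!is.matrix(seqs) || !is.character(seqs)) {
    stop("'seqs' must be a character matrix or named character vector")
  }
  if (is.null(rownames(seqs)) || anyDuplicated(rownames(seqs))) {
    stop("taxon labels (rownames) must be present and unique")
  }
  if (nrow(seqs) < 2) stop("an alignment needs at least 2 sequences")
  if (ncol(seqs) < 1) stop("an alignment needs at least 1 site")
  structure(toupper(seqs), class = c("protein_alignment", "matrix"))
}

#' @rdname protein_alignment
#' @param x A `protein_alignment`.
#' @export
n_sites <- function(x) ncol(x)

#' @export
print.protein_alignment <- function(x, ...) {
  cat(sprintf("Protein alignment: %d taxa x %d sites\n", nrow(x), ncol(x)))
  show <- utils::head(rownames(x), 5)
  for (tx in show) {
    s <- paste(x[tx, seq_len(min(50, ncol(x)))], collapse = "")
    cat(sprintf("  %-12s %s%s\n", tx, s, if (ncol(x) > 50) "..." else ""))
  }
  if (nrow(x) > 5) cat(sprintf("  ... and %d more\n", nrow(x) - 5))
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' @param file Path to an aligned FASTA file (records must be equal length).
#' @return A [protein_alignment()].
#' @export
read_alignment <- function(file) {
  recs <- seqinr::read.fasta(file, seqtype = "AA", as.string = FALSE,
                             set.attributes = FALSE, forceDNAtolower = FALSE)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1) {
    stop("records in ", file, " are not aligned (unequal lengths)")
  }
  m <- do.call(rbind, recs)
  rownames(m) <- names(recs)
  protein_alignment(m)
}

#' Write a protein alignment as FASTA
#'
#' @param aln A [protein_alignment()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_alignment <- function(aln, file) {
  stopifnot(inherits(aln, "protein_alignment"))
  seqinr::write.fasta(
    sequences = lapply(seq_len(nrow(aln)), function(i) aln[i, ]),
    names = rownames(aln), file.out = file, nbchar = 60)
  invisible(file)
}
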