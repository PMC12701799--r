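## An MSA is a character matrix (taxa x sites) of uppercase symbols over
## {A,C,G,T,-} plus IUPAC ambiguity codes, with taxon labels as rownames.

#' Validate and normalize an MSA matrix
#'
#' @param msa character matrix with rownames (taxa) and one column per site.
#' @return the MSA, uppercased.
#' @export
as_msa <- function(msa) {
  stopifnot(is.matrix(msa), is.character(msa))
  if (is.null(rownames(msa)) || anyDuplicated(rownames(msa)))
    stop("MSA needs unique taxon rownames")
  if (ncol(msa) < 1L) stop("MSA needs at least one site")
  toupper(msa)
}

#' Read a FASTA alignment into an MSA matrix
#'
#' Case-insensitive; sequences must be equal length. Gaps are `-`.
#'
#' @param path FASTA file.
#' @return character matrix (taxa x sites).
#' @export
read_fasta_msa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) paste(x, collapse = ""), character(1L))
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences in ", path, " have unequal lengths")
  m <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(m) <- ids
  as_msa(m)
}

#' Write an MSA matrix to FASTA
#'
#' @param msa character matrix.
#' @param path output file.
#' @param width line-wrap width (default 80).
#' @export
write_fasta_msa <- function(msa, path, width = 80L) {
  msa <- as_msa(msa)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(msa))) {
    s <- paste(msa[i, ], collapse = "")
    writeLines(paste0(">", rownames(msa)[i]), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Count distinct site patterns
#'
#' A pattern is a distinct alignment column, with gap and ambiguity characters
#' treated as ordinary symbols (case-normalized).
#'
#' @param msa character matrix.
#' @return integer pattern count.
#' @export
count_patterns <- function(msa) {
  msa <- as_msa(msa)
  cols <- do.call(paste0, lapply(seq_len(nrow(msa)), function(i) msa[i, ]))
  length(unique(cols))
}

#' Fraction of gap cells in an alignment
#'
#' @param msa character matrix.
#' @return numeric in [0, 1].
#' @export
gap_fraction <- function(msa) {
  msa <- as_msa(msa)
  mean(msa == "-")
}

#' Alignment summary statistics
#'
#' Sites, distinct site patterns and gap fraction - the three statistics the
#' indel calibration matches against a target.
#'
#' @param msa character matrix.
#' @return list with `sites`, `patterns`, `gaps`.
#' @export
msa_stats <- function(msa) {
  msa <- as_msa(msa)
  list(sites = ncol(msa), patterns = count_patterns(msa),
       gaps = gap_fraction(msa))
}

#' Superimpose a gap mask onto an alignment
#'
#' Copies `-` into every cell where the template mask is TRUE; used to place
#' empirically observed gap patterns onto freshly simulated gapless
#' alignments. Rows are matched by taxon label.
#'
#' @param msa character matrix.
#' @param template_mask logical matrix of the same shape, rownames matching
#'   the MSA's taxa.
#' @return the masked MSA.
#' @export
superimpose_gaps <- function(msa, template_mask) {
  msa <- as_msa(msa)
  stopifnot(is.logical(template_mask))
  if (!identical(dim(msa), dim(template_mask)))
    stop("mask shape ", paste(dim(template_mask), collapse = "x"),
         " does not match MSA shape ", paste(dim(msa), collapse = "x"))
  if (!is.null(rownames(template_mask))) {
    if (!setequal(rownames(template_mask), rownames(msa)))
      stop("mask taxa do not match MSA taxa")
    template_mask <- template_mask[rownames(msa), , drop = FALSE]
  }
  msa[template_mask] <- "-"
  msa
}

#' Gap mask of an alignment
#'
#' @param msa character matrix.
#' @return logical matrix, TRUE at gap cells.
#' @export
gap_mask <- function(msa) {
  msa <- as_msa(msa)
  msa == "-"
}
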