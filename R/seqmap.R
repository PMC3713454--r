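#' Read sequences from a FASTA file
#' @param path FASTA file
#' @return named character vector of amino-acid sequences
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Pairwise global sequence alignment
#'
#' Needleman-Wunsch alignment through [Biostrings::pairwiseAlignment()]. The
#' default scoring (BLOSUM62, gap open 10, gap extend 0.5, end gaps free) is
#' the conventional choice for aligning full-length homologous ectodomains;
#' percent-identity figures for ErbB ectodomain pairs are insensitive to
#' moderate changes in these parameters at the level of a point or two.
#'
#' @param a,b amino-acid sequences (plain strings)
#' @param matrix substitution matrix name (data set in Biostrings)
#' @param gap_open,gap_ext gap penalties (positive)
#' @param end_gap_free if TRUE (default) terminal gaps are unpenalised
#'   ("overlap" alignment); if FALSE, fully global
#' @return an `AlignmentResult`: list with `a_aln`, `b_aln` (gapped strings),
#'   `score`, and `columns` (data.frame col/ai/bi with NA at gaps)
#' @export
global_align <- function(a, b, matrix = "BLOSUM62", gap_open = 10,
                         gap_ext = 0.5, end_gap_free = TRUE) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  a <- toupper(gsub("\\s", "", a)); b <- toupper(gsub("\\s", "", b))
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = submat, gapOpening = gap_open, gapExtension = gap_ext,
    type = if (end_gap_free) "overlap" else "global")
  a_mid <- as.character(Biostrings::alignedPattern(pa))
  b_mid <- as.character(Biostrings::alignedSubject(pa))
  if (end_gap_free) {
    # "overlap" alignments clip unaligned termini; restore them as
    # terminal-gap columns so degapping either row recovers the full input
    ps <- Biostrings::start(Biostrings::pattern(pa)); pe <- Biostrings::end(Biostrings::pattern(pa))
    ss <- Biostrings::start(Biostrings::subject(pa)); se <- Biostrings::end(Biostrings::subject(pa))
    lead_a <- substr(a, 1, ps - 1); tail_a <- substr(a, pe + 1, nchar(a))
    lead_b <- substr(b, 1, ss - 1); tail_b <- substr(b, se + 1, nchar(b))
    a_aln <- paste0(lead_a, strrep("-", nchar(lead_b)), a_mid,
                    tail_a, strrep("-", nchar(tail_b)))
    b_aln <- paste0(strrep("-", nchar(lead_a)), lead_b, b_mid,
                    strrep("-", nchar(tail_a)), tail_b)
  } else {
    # "global" alignments come back full-length already
    a_aln <- a_mid
    b_aln <- b_mid
  }
  ca <- strsplit(a_aln, "")[[1]]; cb <- strsplit(b_aln, "")[[1]]
  ai <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  bi <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(list(a_aln = a_aln, b_aln = b_aln, score = Biostrings::score(pa),
                 columns = data.frame(col = seq_along(ca), ai = ai, bi = bi)),
            class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: %d columns, score %.1f, identity %.1f%%\n",
              nchar(x$a_aln), x$score, percent_identity(x)))
  invisible(x)
}

#' Write an alignment in a plain-text columnar dump
#' @param aln an AlignmentResult
#' @param path output path
#' @param width characters per block
#' @export
write_alignment <- function(aln, path, width = 60) {
  n <- nchar(aln$a_aln)
  con <- file(path, "w"); on.exit(close(con))
  for (s in seq(1, n, by = width)) {
    e <- min(s + width - 1, n)
    writeLines(c(sprintf("A %6d %s", s, substr(aln$a_aln, s, e)),
                 sprintf("B %6d %s", s, substr(aln$b_aln, s, e)), ""), con)
  }
  invisible(NULL)
}

#' Percent sequence identity of an alignment
#'
#' @param aln an AlignmentResult
#' @param mode denominator: "aligned" = columns between the first and last
#'   column where both sequences have residues (internal gap columns count);
#'   "shorter" = length of the shorter input sequence
#' @return identity percentage (0-100)
#' @export
percent_identity <- function(aln, mode = c("aligned", "shorter")) {
  mode <- match.arg(mode)
  ca <- strsplit(aln$a_aln, "")[[1]]; cb <- strsplit(aln$b_aln, "")[[1]]
  both <- which(ca != "-" & cb != "-")
  if (!length(both)) return(0)
  ident <- sum(ca[both] == cb[both])
  denom <- switch(mode,
                  aligned = max(both) - min(both) + 1,
                  shorter = min(sum(ca != "-"), sum(cb != "-")))
  100 * ident / denom
}

#' Residue equivalence map between two receptors' numbering schemes
#'
#' Built from the non-gap columns of a pairwise alignment. The map is
#' bijective and monotone in both numberings.
#'
#' @param aln an AlignmentResult of receptor A vs receptor B
#' @param numbering_a,numbering_b author residue numbers for the ungapped
#'   sequences (defaults: 1..n)
#' @return an `EquivalenceMap`: data.frame with columns `res_a`, `res_b`
#' @export
build_equivalence <- function(aln, numbering_a = NULL, numbering_b = NULL) {
  cols <- aln$columns
  na_len <- max(cols$ai, na.rm = TRUE); nb_len <- max(cols$bi, na.rm = TRUE)
  if (is.null(numbering_a)) numbering_a <- seq_len(na_len)
  if (is.null(numbering_b)) numbering_b <- seq_len(nb_len)
  if (length(numbering_a) != na_len)
    stop("numbering_a has ", length(numbering_a), " entries; sequence has ", na_len)
  if (length(numbering_b) != nb_len)
    stop("numbering_b has ", length(numbering_b), " entries; sequence has ", nb_len)
  keep <- !is.na(cols$ai) & !is.na(cols$bi)
  out <- data.frame(res_a = numbering_a[cols$ai[keep]],
                    res_b = numbering_b[cols$bi[keep]])
  class(out) <- c("EquivalenceMap", "data.frame")
  out
}

#' Map residue numbers through an equivalence map
#'
#' @param map an EquivalenceMap (A -> B)
#' @param refs residue numbers in A's numbering
#' @return named integer vector of B numbers; residues aligned to a gap are
#'   returned as NA and reported in a warning (never silently dropped)
#' @export
map_residues <- function(map, refs) {
  idx <- match(refs, map$res_a)
  out <- map$res_b[idx]
  names(out) <- refs
  if (anyNA(out))
    warning("unmapped residue(s) (aligned to a gap): ",
            paste(refs[is.na(out)], collapse = ", "))
  out
}

#' Invert an equivalence map (B -> A)
#' @param map an EquivalenceMap
#' @export
invert_equivalence <- function(map) {
  out <- data.frame(res_a = map$res_b, res_b = map$res_a)
  class(out) <- c("EquivalenceMap", "data.frame")
  out
}

#' Export an equivalence map as CSV
#' @param map an EquivalenceMap
#' @param path output path
#' @param chain_a,chain_b chain ids recorded in the CSV
#' @export
write_equivalence_csv <- function(map, path, chain_a = "A", chain_b = "B") {
  utils::write.csv(data.frame(chainA = chain_a, resA = map$res_a,
                              chainB = chain_b, resB = map$res_b),
                   path, row.names = FALSE)
  invisible(NULL)
}
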