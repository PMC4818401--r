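# Breakpoint-junction interpretation: event sizes, shared junction
# motifs, microhomology, flanking-repeat homology, and classification
# of the likely formation mechanism (NAHR / MMEJ / NHEJ).

#' Event size in bp and report kb
#'
#' @param start,end 1-based inclusive breakpoints, `end > start`.
#' @return List `bp` (`end - start + 1`) and `kb` under the report
#'   rounding convention (one decimal below 100 kb, nearest integer
#'   above).
#' @examples
#' event_size(94781525, 94797285)$kb   # 15.8
#' event_size(140390975, 140524875)$kb # 134
#' @export
event_size <- function(start, end) {
  if (end <= start) .fail("end must be greater than start")
  bp <- cnv_length(start, end)
  list(bp = bp, kb = format_kb(bp))
}

.check_dna <- function(x, name) {
  x <- toupper(as.character(x))
  if (grepl("[^ACGTN]", x))
    .fail(name, " contains non-nucleotide characters (allowed: A C G T N)")
  x
}

#' Shared k-mers at the two breakpoint junctions
#'
#' Given the sequences reading away from each breakpoint, reports every
#' k-mer (`k_min <= k <= k_max`) present within `window` bp of both
#' breakpoints, keeping only maximal hits (a k-mer contained in a longer
#' reported shared k-mer is suppressed). `N` never matches. Results are
#' ordered by k descending, then by position at the left junction —
#' deterministic for a given input.
#'
#' @param left_flank_seq,right_flank_seq Junction sequences, each
#'   starting at its breakpoint (characters over `A C G T N`).
#' @param k_min,k_max k-mer size range (defaults 4–20).
#' @param window How far from each breakpoint to scan (default 50 bp);
#'   must not exceed either flank length.
#' @return Data frame `kmer`, `k`, `pos_left`, `pos_right` (1-based
#'   offsets from each breakpoint).
#' @export
junction_motif_scan <- function(left_flank_seq, right_flank_seq,
                                k_min = 4L, k_max = 20L, window = 50L) {
  L <- .check_dna(left_flank_seq, "left_flank_seq")
  R <- .check_dna(right_flank_seq, "right_flank_seq")
  if (window > nchar(L) || window > nchar(R))
    .fail("window exceeds flank length")
  L <- substr(L, 1L, window)
  R <- substr(R, 1L, window)
  k_max <- min(k_max, window)
  hits <- list()
  kept <- character()
  for (k in seq(k_max, max(k_min, 1L), by = -1L)) {
    kl <- substring(L, seq_len(nchar(L) - k + 1L), seq_len(nchar(L) - k + 1L) + k - 1L)
    kr <- substring(R, seq_len(nchar(R) - k + 1L), seq_len(nchar(R) - k + 1L) + k - 1L)
    shared <- setdiff(intersect(kl, kr), kl[grepl("N", kl)])
    for (s in shared) {
      if (any(vapply(kept, function(longer) grepl(s, longer, fixed = TRUE),
                     logical(1))))
        next
      hits[[length(hits) + 1L]] <- data.frame(
        kmer = s, k = k, pos_left = match(s, kl), pos_right = match(s, kr),
        stringsAsFactors = FALSE)
      kept <- c(kept, s)
    }
  }
  res <- if (length(hits)) do.call(rbind, hits) else
    data.frame(kmer = character(), k = integer(), pos_left = integer(),
               pos_right = integer(), stringsAsFactors = FALSE)
  res[order(-res$k, res$pos_left), , drop = FALSE]
}

#' Extract the two junction-adjacent sequences of a deletion
#'
#' Both sequences read rightward from their breakpoint: from the first
#' deleted base, and from the first base after the deletion. Their
#' common prefix is the junction microhomology, and a motif present at
#' both breakpoints appears at position 1 in both.
#'
#' @param ref Reference-allele sequence.
#' @param del_start,del_end Deleted interval (1-based inclusive within
#'   `ref`).
#' @param window Sequence length to extract from each breakpoint.
#' @return List `left`, `right`.
#' @export
junction_flanks <- function(ref, del_start, del_end, window = 50L) {
  ref <- .check_dna(ref, "ref")
  n <- nchar(ref)
  if (del_start < 1L || del_end > n || del_start > del_end)
    .fail("deletion interval out of bounds")
  list(left = substr(ref, del_start, min(n, del_start + window - 1L)),
       right = substr(ref, del_end + 1L, min(n, del_end + window)))
}

#' Junction microhomology length
#'
#' The length of the longest string that is simultaneously a prefix of
#' the sequence beginning at the first deleted base and of the sequence
#' beginning just after the deletion — the standard definition of
#' deletion-junction microhomology on the reference allele.
#'
#' @param ref Reference-allele sequence.
#' @param del_start,del_end Deleted interval (1-based inclusive).
#' @param max_len Cap on the reported length (default 200 bp).
#' @return Microhomology length in bp (0 if the first bases differ).
#' @export
microhomology_length <- function(ref, del_start, del_end, max_len = 200L) {
  ref <- .check_dna(ref, "ref")
  n <- nchar(ref)
  if (del_start < 1L || del_end > n || del_start > del_end)
    .fail("deletion interval out of bounds")
  lim <- min(max_len, del_end - del_start + 1L, n - del_end)
  if (lim <= 0L) return(0L)
  x <- strsplit(substr(ref, del_start, del_start + lim - 1L), "")[[1]]
  y <- strsplit(substr(ref, del_end + 1L, del_end + lim), "")[[1]]
  mism <- which(x != y | x == "N")
  if (length(mism)) mism[1] - 1L else lim
}

#' Homology between the two flanks of a deletion
#'
#' Local (Smith–Waterman) comparison of the upstream and downstream
#' flanking sequences with unit match/mismatch scores and near
#' prohibitive gap penalties, i.e. an effectively ungapped local
#' self-comparison. A long high-identity hit means the deletion is
#' flanked by homologous repeats on both sides — the substrate
#' configuration of non-allelic homologous recombination.
#'
#' @param left_flank,right_flank Sequences upstream of the left
#'   breakpoint and downstream of the right breakpoint.
#' @return List `length` (alignment span, bp), `identity` (fraction),
#'   `both_sides` (`TRUE` for any reported hit: the alignment involves
#'   one segment of each flank), `score`.
#' @export
repeat_homology <- function(left_flank, right_flank) {
  L <- .check_dna(left_flank, "left_flank")
  R <- .check_dna(right_flank, "right_flank")
  if (nchar(L) < 10L || nchar(R) < 10L)
    return(list(length = 0L, identity = 0, both_sides = FALSE, score = 0))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(L, R, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 1000, gapExtension = 1000)
  len <- nchar(as.character(Biostrings::pattern(pa)))
  if (len == 0L)
    return(list(length = 0L, identity = 0, both_sides = FALSE, score = 0))
  list(length = len, identity = Biostrings::pid(pa) / 100,
       both_sides = TRUE, score = Biostrings::score(pa))
}

#' Classify the likely CNV formation mechanism
#'
#' Rule order: NAHR if both flanks share a homologous repeat of at least
#' `min_repeat_len` bp at `min_identity` identity or better; otherwise
#' MMEJ if the junction microhomology is within `mmej_range`; otherwise
#' NHEJ if it is at most 1 bp; otherwise UNCLASSIFIED. The thresholds
#' follow common rearrangement-mechanism conventions, are configurable,
#' and are echoed in the result — they are configuration, not claims
#' about any particular locus.
#'
#' @param microhomology Junction microhomology length (bp).
#' @param repeat_hit A [repeat_homology()] result (or `NULL`).
#' @param min_repeat_len Minimum repeat length for NAHR (default 100 bp).
#' @param min_identity Minimum repeat identity for NAHR (default 0.85).
#' @param mmej_range Microhomology range read as MMEJ (default 2–10 bp).
#' @return List `mechanism` (one of `NAHR`, `MMEJ`, `NHEJ`,
#'   `UNCLASSIFIED`), `rule` (the clause that fired) and `thresholds`.
#' @export
classify_mechanism <- function(microhomology, repeat_hit = NULL,
                               min_repeat_len = 100L, min_identity = 0.85,
                               mmej_range = c(2L, 10L)) {
  thresholds <- list(min_repeat_len = min_repeat_len,
                     min_identity = min_identity, mmej_range = mmej_range)
  if (!is.null(repeat_hit) && isTRUE(repeat_hit$both_sides) &&
      repeat_hit$length >= min_repeat_len &&
      repeat_hit$identity >= min_identity)
    return(list(mechanism = "NAHR",
                rule = sprintf("flanking repeats >= %d bp at >= %.0f%% identity",
                               min_repeat_len, 100 * min_identity),
                thresholds = thresholds))
  if (microhomology >= mmej_range[1] && microhomology <= mmej_range[2])
    return(list(mechanism = "MMEJ",
                rule = sprintf("microhomology in [%d, %d] bp",
                               mmej_range[1], mmej_range[2]),
                thresholds = thresholds))
  if (microhomology <= 1L)
    return(list(mechanism = "NHEJ", rule = "microhomology <= 1 bp",
                thresholds = thresholds))
  list(mechanism = "UNCLASSIFIED",
       rule = "long microhomology without flanking repeats",
       thresholds = thresholds)
}

#' Full junction report for a deletion on its reference allele
#'
#' Computes the event size, the shared breakpoint k-mers, the junction
#' microhomology, the flanking-repeat homology and the mechanism call
#' in one pass.
#'
#' @param ref Reference-allele sequence containing the deletion.
#' @param del_start,del_end Deleted interval (1-based inclusive).
#' @param window Motif-scan window (default 50 bp).
#' @param k_min,k_max Motif-scan k-mer range.
#' @param flank_len How much flanking sequence to use for repeat
#'   detection (default: all available).
#' @param ... Passed to [classify_mechanism()].
#' @return A `junction_report` object.
#' @export
junction_report <- function(ref, del_start, del_end, window = 50L,
                            k_min = 4L, k_max = 20L, flank_len = NULL, ...) {
  ref <- .check_dna(ref, "ref")
  size <- event_size(del_start, del_end)
  fl <- junction_flanks(ref, del_start, del_end, window)
  motifs <- junction_motif_scan(fl$left, fl$right, k_min, k_max,
                                min(window, nchar(fl$left), nchar(fl$right)))
  mh <- microhomology_length(ref, del_start, del_end)
  left_rep <- substr(ref, max(1L, del_start - (flank_len %||% (del_start - 1L))),
                     del_start - 1L)
  right_rep <- substr(ref, del_end + 1L,
                      min(nchar(ref), del_end + (flank_len %||% (nchar(ref) - del_end))))
  rep_hit <- repeat_homology(left_rep, right_rep)
  mech <- classify_mechanism(mh, rep_hit, ...)
  structure(list(size = size, motifs = motifs, microhomology = mh,
                 repeat_homology = rep_hit, mechanism = mech$mechanism,
                 rule = mech$rule, thresholds = mech$thresholds),
            class = "junction_report")
}

#' @export
print.junction_report <- function(x, ...) {
  cat(sprintf("Junction report: %s kb event (%d bp)\n",
              format(x$size$kb), x$size$bp))
  if (nrow(x$motifs))
    cat("  top shared breakpoint k-mer:", x$motifs$kmer[1],
        sprintf("(k=%d)\n", x$motifs$k[1]))
  else cat("  no shared breakpoint k-mer\n")
  cat(sprintf("  microhomology: %d bp; flanking repeat: %d bp at %.1f%% identity\n",
              x$microhomology, x$repeat_homology$length,
              100 * x$repeat_homology$identity))
  cat(sprintf("  mechanism: %s (%s)\n", x$mechanism, x$rule))
  invisible(x)
}
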