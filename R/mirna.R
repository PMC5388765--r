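# Plant-style miRNA target prediction: ungapped complementarity scoring
# with a cumulative expectation penalty (psRNATarget-like; the exact
# constants are exposed in scoring_scheme and documented as this package's
# defaults, not a byte-level reproduction of any external server).

#' Penalty scheme for miRNA-target duplex scoring
#'
#' Each miRNA position (5' to 3') is compared with the complementary
#' position of the target window: a Watson-Crick pair costs 0, a G:U
#' wobble costs `wobble_penalty`, anything else `mismatch_penalty`;
#' penalties inside the core (seed-proximal) region
#' `[core_start, core_end]` are multiplied by `core_multiplier`.  The
#' expectation of a duplex is the sum of its position penalties; duplexes
#' with expectation at most `max_expectation` are reported.
#'
#' @param mismatch_penalty Penalty per mismatching position (default 1).
#' @param wobble_penalty Penalty per G:U wobble (default 0.5).
#' @param core_start,core_end Core region in miRNA coordinates, 1-based
#'   5' to 3' (defaults 2 and 13).
#' @param core_multiplier Factor applied to penalties in the core
#'   (default 2).
#' @param max_expectation Reporting cutoff on the expectation (default 3).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(mismatch_penalty = 1, wobble_penalty = 0.5,
                           core_start = 2L, core_end = 13L,
                           core_multiplier = 2, max_expectation = 3) {
  stopifnot(mismatch_penalty >= 0, wobble_penalty >= 0,
            core_multiplier >= 0, max_expectation >= 0,
            core_start >= 1, core_end >= core_start)
  structure(list(mismatch_penalty = mismatch_penalty,
                 wobble_penalty = wobble_penalty,
                 core_start = as.integer(core_start),
                 core_end = as.integer(core_end),
                 core_multiplier = core_multiplier,
                 max_expectation = max_expectation),
            class = "scoring_scheme")
}

# Pair-type classification for one duplex. mi/tg are DNA-alphabet character
# vectors; mi is 5'->3', tg is the target window 5'->3', so miRNA position i
# pairs with target position L - i + 1.
.pair_labels <- function(mi, tg) {
  target_at <- rev(tg)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  wc <- comp[mi] == target_at
  wobble <- (mi == "G" & target_at == "T") | (mi == "T" & target_at == "G")
  labels <- rep("mismatch", length(mi))
  labels[wobble] <- "wobble"
  labels[wc] <- "match"
  labels
}

.label_penalty <- function(labels, scheme) {
  L <- length(labels)
  pen <- numeric(L)
  pen[labels == "wobble"] <- scheme$wobble_penalty
  pen[labels == "mismatch"] <- scheme$mismatch_penalty
  core <- seq_len(L) >= scheme$core_start &
    seq_len(L) <= min(scheme$core_end, L)
  pen[core] <- pen[core] * scheme$core_multiplier
  pen
}

#' Score one miRNA against one equal-length target window
#'
#' Ungapped mode: the miRNA (5' to 3') is aligned antiparallel to the
#' target window (5' to 3'), so miRNA position i faces target position
#' `length - i + 1`.  T and U are treated as equivalent on both strands.
#'
#' @param mirna_seq miRNA sequence, 5' to 3' (RNA or DNA alphabet).
#' @param target_window Target subsequence of the same length, 5' to 3'.
#' @param scheme A [scoring_scheme()].
#' @return List with `expectation` (cumulative penalty) and
#'   `paired_string`, one character per miRNA position 5' to 3':
#'   `"|"` Watson-Crick match, `"o"` G:U wobble, `"x"` mismatch.
#' @export
#' @examples
#' score_duplex("UGGAGUC", "GACUCCA")  # perfect complement, expectation 0
score_duplex <- function(mirna_seq, target_window,
                         scheme = scoring_scheme()) {
  mi <- .seq_chars(mirna_seq, what = "miRNA sequence")
  tg <- .seq_chars(target_window, what = "target window")
  if (length(mi) != length(tg)) {
    .stopf("ungapped mode needs equal lengths (miRNA %d nt, window %d nt)",
           length(mi), length(tg))
  }
  labels <- .pair_labels(mi, tg)
  glyph <- c(match = "|", wobble = "o", mismatch = "x")
  list(expectation = sum(.label_penalty(labels, scheme)),
       paired_string = paste(glyph[labels], collapse = ""))
}

#' Predict miRNA target sites on transcripts
#'
#' Slides each miRNA over every window of every transcript, scores each
#' window under the scheme, and reports every duplex with expectation at
#' most `scheme$max_expectation`.  The per-(miRNA, transcript) minimum is
#' flagged in column `is_min` (ties: the smallest window start).  Output
#' order is (mirna_id, transcript_id, window_start).
#'
#' @param mirnas Named character vector or [Biostrings::XStringSet] of
#'   miRNA sequences (or a FASTA path).
#' @param transcripts Same forms, for transcript sequences.
#' @param scheme A [scoring_scheme()].
#' @return Data frame: mirna_id, transcript_id, window_start (0-based on
#'   the transcript), expectation, paired_string, is_min.
#' @export
predict_targets <- function(mirnas, transcripts,
                            scheme = scoring_scheme()) {
  mirnas <- .as_named_seqs(mirnas, "miRNA")
  transcripts <- .as_named_seqs(transcripts, "transcript")
  if (!length(mirnas) || !length(transcripts)) {
    .warnf("empty miRNA or transcript set; no duplexes predicted")
    return(.empty_duplexes())
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rows <- list()
  for (mid in names(mirnas)) {
    mi <- .seq_chars(mirnas[[mid]], what = paste("miRNA", mid))
    L <- length(mi)
    mult <- ifelse(seq_len(L) >= scheme$core_start &
                     seq_len(L) <= min(scheme$core_end, L),
                   scheme$core_multiplier, 1)
    for (tid in names(transcripts)) {
      tg <- .seq_chars(transcripts[[tid]], what = paste("transcript", tid))
      n <- length(tg)
      if (n < L) next
      n_win <- n - L + 1L
      # target base faced by miRNA position i in the window starting at s
      # (0-based) is tg[s + L - i + 1]
      idx <- outer(L - seq_len(L) + 1L, 0:(n_win - 1L), `+`)
      tmat <- matrix(tg[idx], nrow = L)
      wc <- tmat == comp[mi]
      wobble <- (mi == "G" & tmat == "T") | (mi == "T" & tmat == "G")
      pen <- matrix(scheme$mismatch_penalty, nrow = L, ncol = n_win)
      pen[wobble] <- scheme$wobble_penalty
      pen[wc] <- 0
      e <- colSums(pen * mult)
      hit <- which(e <= scheme$max_expectation)
      if (!length(hit)) next
      ps <- vapply(hit, function(s) {
        labels <- rep("x", L)
        labels[wobble[, s]] <- "o"
        labels[wc[, s]] <- "|"
        paste(labels, collapse = "")
      }, character(1))
      # the per-pair minimum is always <= cutoff when any window is, so the
      # flagged row is the global minimum for the pair; ties -> first start
      is_min <- rep(FALSE, length(hit))
      is_min[which.min(e[hit])] <- TRUE
      rows[[length(rows) + 1]] <- data.frame(
        mirna_id = mid, transcript_id = tid,
        window_start = hit - 1L, expectation = e[hit],
        paired_string = ps, is_min = is_min,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(.empty_duplexes())
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_id, out$transcript_id, out$window_start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_duplexes <- function() {
  data.frame(mirna_id = character(0), transcript_id = character(0),
             window_start = integer(0), expectation = numeric(0),
             paired_string = character(0), is_min = logical(0),
             stringsAsFactors = FALSE)
}

.as_named_seqs <- function(x, what) {
  if (is.character(x) && length(x) == 1 && file.exists(x) &&
      is.null(names(x))) {
    x <- Biostrings::readBStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    x <- setNames(as.character(x), names(x))
  }
  if (length(x) && (is.null(names(x)) || any(!nzchar(names(x))))) {
    .stopf("%s sequences must be named", what)
  }
  x
}

#' Collapse duplexes to miRNA-gene edges
#'
#' One edge per (miRNA, gene) at the minimum expectation over that gene's
#' transcripts.  Transcripts without a gene mapping produce an edge to the
#' transcript id with a warning.
#'
#' @param duplexes Data frame from [predict_targets()].
#' @param gene_map Data frame with columns transcript_id, gene_id (or a
#'   named character vector transcript -> gene).
#' @return Data frame: mirna_id, gene_id, expectation, ordered by
#'   (mirna_id, gene_id).
#' @export
mirna_edges <- function(duplexes, gene_map = NULL) {
  if (nrow(duplexes) == 0) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      expectation = numeric(0), stringsAsFactors = FALSE))
  }
  map <- if (is.null(gene_map)) {
    setNames(character(0), character(0))
  } else if (is.data.frame(gene_map)) {
    setNames(gene_map$gene_id, gene_map$transcript_id)
  } else {
    gene_map
  }
  gene <- unname(map[duplexes$transcript_id])
  unmapped <- is.na(gene)
  if (any(unmapped)) {
    .warnf("%d duplex(es) on transcripts without a gene mapping (e.g. %s)",
           sum(unmapped), duplexes$transcript_id[unmapped][1])
    gene[unmapped] <- duplexes$transcript_id[unmapped]
  }
  key <- paste(duplexes$mirna_id, gene, sep = "\r")
  best <- tapply(duplexes$expectation, key, min)
  parts <- strsplit(names(best), "\r", fixed = TRUE)
  out <- data.frame(
    mirna_id = vapply(parts, `[`, character(1), 1),
    gene_id = vapply(parts, `[`, character(1), 2),
    expectation = unname(as.numeric(best)),
    stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
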