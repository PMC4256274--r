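#' Scanner configuration
#'
#' Parameters of the slippery-site scan. Defaults are chosen to capture the
#' characterised sites (runs of 9 and 11 adenosines) with margin: a minimum
#' run length of 8, a stop-search window of 60 nt (roughly twice the one
#' measured run-to-stop distance of 28 nt), and candidate net edits
#' k in {-2,-1,+1,+2}.
#'
#' @param min_run_length Minimum homopolymer run length to report (>= 4).
#' @param bases Bases scanned on the coding strand; T-runs flag potential
#'   template-strand slippage.
#' @param max_distance Maximum nt between run end and premature stop start
#'   (exclusive of both) for a run to be called a candidate site.
#' @param k_set Net A insertions (negative = deletions) tested for
#'   reading-frame restoration.
#' @param abnormal_length_fraction A family member is flagged
#'   abnormal-length when its CDS is shorter than this fraction of the family
#'   median length.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(min_run_length = 8L, bases = c("A", "T"),
                        max_distance = 60L, k_set = c(-2L, -1L, 1L, 2L),
                        abnormal_length_fraction = 0.8) {
  if (min_run_length < 4L) stop("`min_run_length` must be >= 4", call. = FALSE)
  if (!all(bases %in% c("A", "T"))) stop("`bases` must be among A, T", call. = FALSE)
  if (max_distance < 1L) stop("`max_distance` must be positive", call. = FALSE)
  if (abnormal_length_fraction <= 0 || abnormal_length_fraction >= 1)
    stop("`abnormal_length_fraction` must lie in (0, 1)", call. = FALSE)
  structure(list(min_run_length = as.integer(min_run_length), bases = bases,
                 max_distance = as.integer(max_distance),
                 k_set = as.integer(k_set),
                 abnormal_length_fraction = abnormal_length_fraction),
            class = "scan_config")
}

#' Find maximal homopolymer runs
#'
#' Scans the coding strand for maximal runs of a given base of at least
#' `min_length` consecutive occurrences. U is treated as T, so RNA input is
#' scanned with the same base alphabet.
#'
#' @param x A [cds()].
#' @param base Base(s) to scan for, among `"A"`, `"T"`.
#' @param min_length Minimum run length reported.
#' @return A tibble with columns `seq_id`, `base`, `start` (1-based),
#'   `length`, sorted by `start`. Maximality guarantees reported runs do not
#'   overlap.
#' @examples
#' rna <- cds("GCCGGCUAUUAUGAGGCGUUUAAAAAAAAAAAUGGGUCCGGGGCUGAUGCUGUUAG",
#'            id = "synthetic-56nt")
#' find_runs(rna, base = "A", min_length = 8)
#' @export
find_runs <- function(x, base = c("A", "T"), min_length = 8L) {
  assert_cds(x)
  base <- match.arg(base, c("A", "T"), several.ok = TRUE)
  v <- strsplit(chartr("U", "T", x$seq), "", fixed = TRUE)[[1L]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values %in% base & r$lengths >= min_length
  tibble::tibble(seq_id = x$id,
                 base = r$values[keep],
                 start = starts[keep],
                 length = r$lengths[keep])
}

#' Position of the first premature in-frame stop codon
#'
#' Reads frame-0 codons from nucleotide 1 (the sequence is assumed to start
#' at the annotated start codon) and returns the 1-based position of the
#' first nucleotide of the first stop codon lying strictly before the final
#' complete codon. A stop occupying the final codon is a normal terminator,
#' not premature.
#'
#' @param x A [cds()].
#' @return Integer position, or `NA` if the only stop is terminal; `NA` with
#'   a warning if the frame contains no stop at all.
#' @examples
#' find_premature_stop(cds("ATGAAATAGAAATAA"))  # 7
#' find_premature_stop(cds("ATGAAATAA"))        # NA: terminal stop only
#' @export
find_premature_stop <- function(x) {
  assert_cds(x)
  cod <- codons_from(chartr("U", "T", x$seq))
  hits <- which(cod %in% .STOP_CODONS)
  if (length(hits) == 0L) {
    warning("no in-frame stop codon found in ", x$id, call. = FALSE)
    return(NA_integer_)
  }
  if (hits[1L] == length(cod)) return(NA_integer_)
  3L * (hits[1L] - 1L) + 1L
}

# Does translation of `edited` (a cds translated from nt 1, frame 0) extend
# past the parent's premature stop codon, whose start in edited coordinates
# is stop_start + k (the edit lies upstream of the stop)?
translation_passes <- function(edited, stop_start_edited) {
  p <- translate_cds(edited)
  end_nt <- 3L * p$length_aa + if (p$terminated) 3L else 0L
  end_nt > stop_start_edited + 2L
}

#' Call candidate transcriptional slippery sites
#'
#' A slippery site pairs a homopolymer run with a premature in-frame stop
#' codon lying at most `max_distance` nt downstream of the run. For each site
#' the restoring edit set is computed: the net A insertions/deletions k in
#' `k_set` whose edited transcript translates past the premature stop.
#'
#' @param x A [cds()].
#' @param config A [scan_config()].
#' @return A tibble with columns `seq_id`, `base`, `run_start`, `run_length`,
#'   `stop_start`, `distance` (nt strictly between run end and stop start),
#'   and list-column `restoring_edits`; sorted by distance ascending, ties by
#'   run length descending.
#' @export
call_slippery_sites <- function(x, config = scan_config()) {
  assert_cds(x)
  stopifnot(inherits(config, "scan_config"))
  empty <- tibble::tibble(seq_id = character(), base = character(),
                          run_start = integer(), run_length = integer(),
                          stop_start = integer(), distance = integer(),
                          restoring_edits = list())
  runs <- find_runs(x, base = config$bases, min_length = config$min_run_length)
  if (nrow(runs) == 0L) return(empty)
  stop_start <- suppressWarnings(find_premature_stop(x))
  if (is.na(stop_start)) return(empty)

  run_end <- runs$start + runs$length - 1L
  dist <- stop_start - run_end - 1L
  keep <- dist >= 0L & dist <= config$max_distance
  runs <- runs[keep, , drop = FALSE]
  dist <- dist[keep]
  if (nrow(runs) == 0L) return(empty)

  edits <- lapply(seq_len(nrow(runs)), function(i) {
    run <- runs[i, ]
    ks <- config$k_set[config$k_set > -run$length]
    restoring <- vapply(ks, function(k) {
      ed <- apply_slippage_edit(x, run, k)
      translation_passes(cds(ed$edited_seq, id = x$id, source = x$source),
                         stop_start + k)
    }, logical(1))
    sort(ks[restoring])
  })

  out <- tibble::tibble(seq_id = runs$seq_id, base = runs$base,
                        run_start = runs$start, run_length = runs$length,
                        stop_start = stop_start, distance = dist,
                        restoring_edits = edits)
  out[order(out$distance, -out$run_length), , drop = FALSE]
}

#' Screen a gene family for abnormal lengths and slippery sites
#'
#' Applies the two-pronged family screen: flag members whose CDS is
#' substantially shorter than the family median (a premature stop truncating
#' the annotated ORF), and report homopolymeric A/T runs and candidate
#' slippery sites per member.
#'
#' @param members A list of [cds()] (at least 3, so the median is
#'   meaningful).
#' @param config A [scan_config()].
#' @return A tibble with one row per member, sorted by id: `id`, `length_nt`,
#'   `abnormal_length`, `n_runs`, `max_run_length`, `n_sites`.
#' @export
screen_family <- function(members, config = scan_config()) {
  if (!is.list(members) || length(members) < 3L)
    stop("family screen needs at least 3 members", call. = FALSE)
  lapply(members, assert_cds)
  lens <- vapply(members, function(m) m$length, numeric(1))
  med <- stats::median(lens)
  rows <- lapply(members, function(m) {
    runs <- find_runs(m, base = config$bases,
                      min_length = config$min_run_length)
    sites <- call_slippery_sites(m, config)
    tibble::tibble(id = m$id, length_nt = m$length,
                   abnormal_length =
                     m$length < config$abnormal_length_fraction * med,
                   n_runs = nrow(runs),
                   max_run_length = if (nrow(runs)) max(runs$length) else 0L,
                   n_sites = nrow(sites))
  })
  out <- do.call(rbind, rows)
  out[order(out$id), , drop = FALSE]
}
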