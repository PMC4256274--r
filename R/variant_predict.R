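# Average residue masses (Da): amino-acid monomer minus one water, standard
# average isotopic composition. One water is added back per chain.
.AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0513,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.0153

#' Apply a slippage edit to a transcript
#'
#' Models the outcome of transcriptional slippage at a homopolymer run: a net
#' insertion of `k` copies of the run base (k > 0), a net deletion of |k|
#' bases (k < 0), or the unedited transcript (k = 0). Because insertions
#' within a homopolymer are indistinguishable at sequence level, edits are
#' canonically placed at the run's 3' end.
#'
#' @param x A [cds()].
#' @param run A single run as returned by [find_runs()] (fields `start`,
#'   `length`, `base`), belonging to `x`.
#' @param k Net inserted base count; deletions must leave at least one run
#'   base (`k >= -(run$length - 1)`).
#' @return A list of class `transcript_edit`: `parent_id`, `k`,
#'   `edit_position` (1-based nt of the last original run base), and
#'   `edited_seq`.
#' @examples
#' x <- cds("CCAAAAAAAAAAAGG", id = "toy")
#' run <- find_runs(x, "A", min_length = 8)
#' nchar(apply_slippage_edit(x, run, +1)$edited_seq)  # parent + 1
#' @export
apply_slippage_edit <- function(x, run, k) {
  assert_cds(x)
  if (is.data.frame(run)) {
    if (nrow(run) != 1L) stop("`run` must be a single run", call. = FALSE)
    run <- as.list(run)
  }
  k <- as.integer(k)
  run_end <- run$start + run$length - 1L
  if (run$start < 1L || run_end > x$length)
    stop("run does not fit inside the sequence", call. = FALSE)
  seg <- chartr("U", "T", substr(x$seq, run$start, run_end))
  if (seg != strrep(run$base, run$length))
    stop("run does not match the sequence at its coordinates", call. = FALSE)
  if (k < -(run$length - 1L))
    stop("deletion would remove the entire run", call. = FALSE)
  # insertions use the stored-alphabet letter so RNA stays RNA
  letter <- if (x$alphabet == "RNA" && run$base == "T") "U" else run$base
  left <- substr(x$seq, 1L, run_end)
  right <- substr(x$seq, run_end + 1L, x$length)
  edited <- if (k >= 0L) {
    paste0(left, strrep(letter, k), right)
  } else {
    paste0(substr(x$seq, 1L, run_end + k), right)
  }
  structure(list(parent_id = x$id, k = k, edit_position = run_end,
                 edited_seq = edited),
            class = "transcript_edit")
}

#' Predict the protein variants produced by slippage at a run
#'
#' For each net edit k (k = 0 is always included), the edited transcript is
#' translated from nucleotide 1 until the first stop, and the variant's
#' length, average molecular mass and restoration status are reported. A
#' variant is `full_length_restored` when its translation extends past the
#' parent's premature stop codon — i.e. the edit shifted the ribosome into a
#' frame lacking that stop.
#'
#' @param x A [cds()] starting at its start codon.
#' @param run A single run from [find_runs()].
#' @param k_set Integer edits to evaluate; 0 is added if absent.
#' @return A tibble ordered by k: `seq_id`, `k`, `length_aa`, `mw_kda`,
#'   `terminated`, `full_length_restored` (`NA` when the parent has no
#'   premature stop).
#' @export
predict_variants <- function(x, run, k_set = c(-2L, -1L, 1L, 2L)) {
  assert_cds(x)
  k_set <- sort(unique(c(0L, as.integer(k_set))))
  stop_start <- suppressWarnings(find_premature_stop(x))
  rows <- lapply(k_set, function(k) {
    ed <- apply_slippage_edit(x, run, k)
    exd <- cds(ed$edited_seq, id = x$id, source = x$source)
    p <- translate_cds(exd)
    restored <- if (is.na(stop_start)) NA else
      translation_passes(exd, stop_start + k)
    tibble::tibble(seq_id = x$id, k = k, length_aa = p$length_aa,
                   mw_kda = protein_mw(p), terminated = p$terminated,
                   full_length_restored = restored)
  })
  do.call(rbind, rows)
}

#' Average molecular mass of a protein, in kDa
#'
#' Sum of average amino-acid residue masses plus one water. Average (not
#' monoisotopic) masses are used, matching how apparent sizes on SDS-PAGE and
#' deconvoluted ESI masses are usually quoted.
#'
#' @param p A [protein_seq()] or a plain one-letter residue string.
#' @return Mass in kDa (0, with a warning, for an empty protein).
#' @examples
#' protein_mw("G")  # 0.0750666 kDa: glycine residue 57.0513 + water 18.0153
#' @export
protein_mw <- function(p) {
  res <- if (inherits(p, "protein_seq")) p$residues else toupper(p)
  if (!nzchar(res)) {
    warning("empty protein: mass 0", call. = FALSE)
    return(0)
  }
  aa <- strsplit(res, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(aa), names(.AA_RESIDUE_MASS))
  if (length(bad) > 0L)
    stop("unknown residue(s): ", paste(bad, collapse = ", "), call. = FALSE)
  (sum(.AA_RESIDUE_MASS[aa]) + .WATER_MASS) / 1000
}
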