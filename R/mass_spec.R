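# Average nucleotide residue masses (Da): nucleoside-5'-monophosphate minus
# one water, i.e. the per-residue increment inside an oligo chain.
.DNA_RESIDUE_MASS <- c(A = 313.21, C = 289.18, G = 329.21, T = 304.20)
.RNA_RESIDUE_MASS <- c(A = 329.21, C = 305.18, G = 345.21, U = 306.17)
.OLIGO_WATER <- 18.02
.HPO3_MASS <- 79.98

#' Construct an oligonucleotide
#'
#' @param seq Nucleotide string; alphabet must match `kind`.
#' @param kind `"ssDNA"` or `"ssRNA"`.
#' @param five_prime_end `"hydroxyl"` (default, standard unphosphorylated
#'   PCR primers) or `"phosphate"`.
#' @return A list of class `oligo`.
#' @export
oligo <- function(seq, kind = c("ssDNA", "ssRNA"),
                  five_prime_end = c("hydroxyl", "phosphate")) {
  kind <- match.arg(kind)
  five_prime_end <- match.arg(five_prime_end)
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty oligonucleotide", call. = FALSE)
  allowed <- if (kind == "ssDNA") "[^ACGT]" else "[^ACGU]"
  if (grepl(allowed, s))
    stop("sequence alphabet does not match ", kind, call. = FALSE)
  structure(list(seq = s, kind = kind, five_prime_end = five_prime_end),
            class = "oligo")
}

#' Average neutral mass of an oligonucleotide
#'
#' Sum of per-residue average masses, plus one water for a 5'-hydroxyl
#' terminus or additionally one HPO3 for a 5'-phosphate. Neutral (uncharged)
#' species are assumed: charge-state deconvolution is taken to have been done
#' by the instrument software.
#'
#' @param o An [oligo()], or a string (taken as 5'-OH ssDNA).
#' @return Average mass in Da.
#' @examples
#' oligo_average_mass("A")  # 313.21 + 18.02 = 331.23 Da
#' @export
oligo_average_mass <- function(o) {
  if (is.character(o)) o <- oligo(o)
  stopifnot(inherits(o, "oligo"))
  tab <- if (o$kind == "ssDNA") .DNA_RESIDUE_MASS else .RNA_RESIDUE_MASS
  bases <- strsplit(o$seq, "", fixed = TRUE)[[1L]]
  m <- sum(tab[bases]) + .OLIGO_WATER
  if (o$five_prime_end == "phosphate") m <- m + .HPO3_MASS
  round(m, 2)
}

#' Predict the mass ladder of amplicons over a resized homopolymer run
#'
#' Transcriptional slippage yields a heterogeneous population of mRNAs whose
#' RT-PCR products differ by single A residues in the run. This builds the
#' predicted average-mass ladder: for each A count, the amplicon bounded by
#' `amplicon_start`..`amplicon_end` (1-based, inclusive, bracketing the run)
#' has its run resized to that count, and both duplex strands are massed as
#' independent single strands (sense, and its reverse complement as
#' antisense). RNA templates are amplified as DNA.
#'
#' @param template A [cds()] containing the run.
#' @param run A single run from [find_runs()].
#' @param amplicon_start,amplicon_end Amplicon bounds on the template; they
#'   must bracket the run.
#' @param a_counts Integer vector of run sizes to ladder over.
#' @param five_prime_end End chemistry passed to [oligo()].
#' @return A tibble of class `mass_ladder`: `strand` (`sense`/`antisense`),
#'   `a_count`, `length_nt`, `mass_da`. Within a strand, consecutive entries
#'   differ by one dA (sense, 313.21 Da) or one dT (antisense, 304.20 Da)
#'   residue mass.
#' @export
build_ladder <- function(template, run, amplicon_start, amplicon_end,
                         a_counts, five_prime_end = "hydroxyl") {
  assert_cds(template)
  if (is.data.frame(run)) run <- as.list(run[1L, ])
  run_end <- run$start + run$length - 1L
  if (amplicon_start < 1L || amplicon_end > template$length ||
      amplicon_start > run$start || amplicon_end < run_end)
    stop("amplicon bounds must bracket the run", call. = FALSE)
  a_counts <- sort(unique(as.integer(a_counts)))
  if (any(a_counts < 1L)) stop("a_counts must be >= 1", call. = FALSE)
  s <- chartr("U", "T", template$seq)
  left <- substr(s, amplicon_start, run$start - 1L)
  right <- substr(s, run_end + 1L, amplicon_end)
  rows <- lapply(a_counts, function(a) {
    sense <- paste0(left, strrep(run$base, a), right)
    anti <- reverse_complement(sense)
    tibble::tibble(
      strand = c("sense", "antisense"),
      a_count = a,
      length_nt = nchar(sense),
      mass_da = c(
        oligo_average_mass(oligo(sense, "ssDNA", five_prime_end)),
        oligo_average_mass(oligo(anti, "ssDNA", five_prime_end))))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mass_ladder", class(out))
  out
}

#' Assign measured ESI/MS peaks to ladder entries
#'
#' Each measured neutral mass is assigned to the nearest predicted ladder
#' mass; the percentage error `100 * (measured - predicted) / predicted` is
#' reported, and peaks whose |error| exceeds `tolerance_pct` are flagged
#' unassigned (their nearest entry is still shown).
#'
#' @param measured Numeric vector of measured neutral masses (Da).
#' @param ladder A [build_ladder()] result.
#' @param tolerance_pct Maximum |percentage error| for a confident
#'   assignment. Default 0.02.
#' @return A tibble ordered by measured mass: `measured_mass`,
#'   `assigned_strand`, `assigned_a_count`, `predicted_mass`, `pct_error`,
#'   `assigned`.
#' @export
assign_peaks <- function(measured, ladder, tolerance_pct = 0.02) {
  if (!is.data.frame(ladder) || nrow(ladder) == 0L)
    stop("empty mass ladder", call. = FALSE)
  if (tolerance_pct <= 0) stop("`tolerance_pct` must be > 0", call. = FALSE)
  measured <- sort(as.numeric(measured))
  rows <- lapply(measured, function(m) {
    i <- which.min(abs(ladder$mass_da - m))
    pred <- ladder$mass_da[i]
    err <- 100 * (m - pred) / pred
    tibble::tibble(measured_mass = m,
                   assigned_strand = ladder$strand[i],
                   assigned_a_count = ladder$a_count[i],
                   predicted_mass = pred,
                   pct_error = err,
                   assigned = abs(err) <= tolerance_pct)
  })
  if (length(rows) == 0L)
    return(tibble::tibble(measured_mass = numeric(),
                          assigned_strand = character(),
                          assigned_a_count = integer(),
                          predicted_mass = numeric(),
                          pct_error = numeric(), assigned = logical()))
  do.call(rbind, rows)
}
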