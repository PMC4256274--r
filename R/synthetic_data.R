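# Designed slippery-site genes and the stochastic slippage simulator.
#
# The generator emulates the architecture of a slippage-rescued gene: an ORF
# whose frame-0 reading ends at a premature amber stop a fixed distance
# downstream of a poly-A run, with a +1-frame ORF continuing past that stop,
# so a net +1 insertion in the run restores a full-length product.

.SAFE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
}

#' Specify a slippery-site gene design
#'
#' Defaults reproduce the characterised architecture: 794 codons upstream of
#' an 11-A run at a codon boundary place the premature amber stop at nt
#' 2,422-2,424 (so the truncated product is 807 aa and its ORF including the
#' stop is 2,424 nt), the run ends 28 nt upstream of the stop, and 321 codons
#' readable in the +1 frame past the stop yield a 1,129-aa restored product.
#'
#' @param upstream_codons Codons before the run, including the start codon.
#' @param run_length Length of the designed poly-A run.
#' @param spacer_nt Nucleotides strictly between the run end and the
#'   premature stop start. `run_length + spacer_nt` must be a multiple of 3
#'   so the designed stop lands in frame 0 with the run at a codon boundary.
#' @param plus1_orf_codons Codons read in the +1 frame past the premature
#'   stop before the designed +1-frame terminator. With 0, the +1 frame is
#'   closed by a designed stop inside the spacer, so a +1 edit is *not*
#'   restoring (requires `spacer_nt` large enough to hold it).
#' @param seed Seed making the design deterministic.
#' @return A list of class `gene_design`.
#' @export
gene_design <- function(upstream_codons = 794L, run_length = 11L,
                        spacer_nt = 28L, plus1_orf_codons = 321L,
                        seed = 1L) {
  upstream_codons <- as.integer(upstream_codons)
  run_length <- as.integer(run_length)
  spacer_nt <- as.integer(spacer_nt)
  plus1_orf_codons <- as.integer(plus1_orf_codons)
  if (upstream_codons < 1L) stop("need at least the start codon upstream", call. = FALSE)
  if (run_length < 4L) stop("`run_length` must be >= 4", call. = FALSE)
  if (spacer_nt < 0L) stop("`spacer_nt` must be >= 0", call. = FALSE)
  if ((run_length + spacer_nt) %% 3L != 0L)
    stop("`run_length + spacer_nt` must be a multiple of 3 ",
         "(premature stop must be in frame 0)", call. = FALSE)
  comp_len <- (3L - run_length %% 3L) %% 3L
  if (plus1_orf_codons == 0L && spacer_nt < comp_len + 6L)
    stop("`spacer_nt` too short to hold the designed +1-frame stop", call. = FALSE)
  structure(list(upstream_codons = upstream_codons, run_length = run_length,
                 spacer_nt = spacer_nt, plus1_orf_codons = plus1_orf_codons,
                 seed = as.integer(seed)),
            class = "gene_design")
}

# one construction attempt; invariants are verified afterwards
build_gene_attempt <- function(d) {
  u <- d$upstream_codons
  upstream <- c("ATG", sample(.SAFE_CODONS, u - 1L, replace = TRUE))
  if (u > 1L) {
    no_a_end <- .SAFE_CODONS[substr(.SAFE_CODONS, 3L, 3L) != "A"]
    upstream[u] <- sample(no_a_end, 1L)
  }
  run <- strrep("A", d$run_length)
  comp_len <- (3L - d$run_length %% 3L) %% 3L
  comp <- if (comp_len > 0L)
    paste(c(sample(c("C", "G"), 1L),
            sample(c("A", "C", "G", "T"), comp_len - 1L, replace = TRUE)),
          collapse = "") else ""
  n_spacer_codons <- (d$spacer_nt - comp_len) %/% 3L
  spacer_codons <- if (n_spacer_codons > 0L) {
    sc <- sample(.SAFE_CODONS, n_spacer_codons, replace = TRUE)
    if (comp_len == 0L) {
      no_a_start <- .SAFE_CODONS[substr(.SAFE_CODONS, 1L, 1L) != "A"]
      sc[1L] <- sample(no_a_start, 1L)
    }
    if (d$plus1_orf_codons == 0L) {
      # close the +1 frame inside the spacer: +1-frame codon (b3 of codon j,
      # b1 b2 of codon j+1) set to TAA; neither host codon can become a stop
      sc[1L] <- paste0(sample(c("C", "G"), 1L),
                       sample(c("A", "C", "G", "T"), 1L), "T")
      sc[2L] <- paste0("AA", sample(c("C", "G", "T"), 1L))
      if (comp_len == 0L && substr(sc[1L], 1L, 1L) == "A")
        sc[1L] <- paste0("C", substr(sc[1L], 2L, 3L))
    }
    sc
  } else character(0)
  downstream <- if (d$plus1_orf_codons > 0L) {
    d12 <- paste(sample(c("C", "G", "T"), 2L, replace = TRUE), collapse = "")
    body <- if (d$plus1_orf_codons > 1L)
      paste(sample(.SAFE_CODONS, d$plus1_orf_codons - 1L, replace = TRUE),
            collapse = "") else ""
    paste0(d12, body, "TAA")
  } else {
    paste0(paste(sample(.SAFE_CODONS, 3L, replace = TRUE), collapse = ""), "TAA")
  }
  paste0(paste(upstream, collapse = ""), run, comp,
         paste(spacer_codons, collapse = ""), "TAG", downstream)
}

check_designed_gene <- function(g, d) {
  run_start <- 3L * d$upstream_codons + 1L
  stop_start <- run_start + d$run_length + d$spacer_nt
  scan_min <- min(8L, d$run_length)
  runs_a <- find_runs(g, "A", min_length = scan_min)
  runs_t <- find_runs(g, "T", min_length = 8L)
  if (nrow(runs_t) > 0L) return(FALSE)
  if (nrow(runs_a) != 1L || runs_a$start != run_start ||
      runs_a$length != d$run_length) return(FALSE)
  ps <- suppressWarnings(find_premature_stop(g))
  if (is.na(ps) || ps != stop_start) return(FALSE)
  trunc_aa <- (stop_start - 1L) %/% 3L
  p0 <- translate_cds(g)
  if (!p0$terminated || p0$length_aa != trunc_aa) return(FALSE)
  run <- list(start = run_start, length = d$run_length, base = "A")
  ed <- apply_slippage_edit(g, run, +1L)
  gp1 <- cds(ed$edited_seq, id = g$id)
  pp1 <- translate_cds(gp1)
  if (d$plus1_orf_codons > 0L) {
    full_aa <- (stop_start + 2L) %/% 3L + d$plus1_orf_codons
    if (!pp1$terminated || pp1$length_aa != full_aa) return(FALSE)
    if (!translation_passes(gp1, stop_start + 1L)) return(FALSE)
  } else {
    if (translation_passes(gp1, stop_start + 1L)) return(FALSE)
  }
  TRUE
}

#' Generate a designed slippery-site gene
#'
#' Builds a coding sequence satisfying every design invariant: the first
#' frame-0 stop is the designed premature stop, the only A/T homopolymer of
#' scannable length is the designed run, and the +1 frame is open exactly to
#' the designed terminus (so a +1 edit is restoring iff `plus1_orf_codons >
#' 0`). Construction is by bounded rejection sampling and is deterministic
#' under the design's seed.
#'
#' @param d A [gene_design()].
#' @param id,source Identity recorded on the generated [cds()].
#' @return A list of class `designed_gene`: `cds`, `run` (one-row tibble as
#'   from [find_runs()]), `premature_stop` (1-based nt of the stop codon's
#'   first nt), `truncated_aa`, `full_aa` (`NA` when `plus1_orf_codons = 0`),
#'   and the `design`.
#' @examples
#' g <- design_gene(gene_design(upstream_codons = 10, plus1_orf_codons = 5))
#' g$truncated_aa
#' @export
design_gene <- function(d = gene_design(), id = "synthetic_tssM_like",
                        source = "synthetic") {
  stopifnot(inherits(d, "gene_design"))
  g <- withr::with_seed(d$seed, {
    ok <- NULL
    for (attempt in seq_len(200L)) {
      cand <- cds(build_gene_attempt(d), id = id, source = source)
      if (check_designed_gene(cand, d)) {
        ok <- cand
        break
      }
    }
    ok
  })
  if (is.null(g))
    stop("gene design infeasible after 200 attempts", call. = FALSE)
  run_start <- 3L * d$upstream_codons + 1L
  stop_start <- run_start + d$run_length + d$spacer_nt
  structure(list(
    cds = g,
    run = tibble::tibble(seq_id = g$id, base = "A",
                         start = run_start, length = d$run_length),
    premature_stop = stop_start,
    truncated_aa = (stop_start - 1L) %/% 3L,
    full_aa = if (d$plus1_orf_codons > 0L)
      (stop_start + 2L) %/% 3L + d$plus1_orf_codons else NA_integer_,
    design = d), class = "designed_gene")
}

#' Specify a per-transcript slippage model
#'
#' Each transcript acquires a single net edit k drawn from this distribution
#' — a deliberate simplification of per-step polymerase realignment that
#' still reproduces a heterogeneous A-count population. The support
#' `{-1..+4}` spans run sizes 10-15 around a native 11-A run.
#'
#' @param probabilities Named numeric vector of probabilities keyed by k
#'   (names coercible to integers in -1..4). Any unassigned remainder is
#'   placed on k = 0. Default: `c("1" = 0.25)`, i.e. 25% +1 slippage.
#' @return A list of class `slippage_model` with `k` and `p`.
#' @export
slippage_model <- function(probabilities = c("1" = 0.25)) {
  support <- -1L:4L
  p <- stats::setNames(numeric(length(support)), as.character(support))
  if (length(probabilities) > 0L) {
    ks <- suppressWarnings(as.integer(names(probabilities)))
    if (anyNA(ks) || !all(ks %in% support))
      stop("model support is k in -1..4", call. = FALSE)
    if (any(probabilities < 0)) stop("probabilities must be >= 0", call. = FALSE)
    p[as.character(ks)] <- probabilities
  }
  rest <- 1 - sum(p[names(p) != "0"])
  if (rest < -1e-12) stop("probabilities sum to more than 1", call. = FALSE)
  if (!("0" %in% names(probabilities))) p["0"] <- rest
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1", call. = FALSE)
  structure(list(k = support, p = unname(p)), class = "slippage_model")
}

#' Simulate a slipped transcript population
#'
#' Draws one net edit k per transcript from the model, translates each
#' distinct edited mRNA, and assembles the population: counts per k, per
#' A-count, and per protein-variant length, plus the realized fraction of
#' transcripts whose translation passes the premature stop.
#'
#' @param gene A [design_gene()] result (or a list with `cds`, `run`, and
#'   `premature_stop`).
#' @param model A [slippage_model()].
#' @param n Number of transcripts (>= 1).
#' @param seed Seed for the per-transcript draws.
#' @return A list of class `simulated_population`: `n_transcripts`,
#'   `variants` (tibble: `k`, `a_count`, `length_aa`, `restored`, `count`),
#'   `a_count_counts`, `variant_counts` (named by length), and
#'   `true_restoring_fraction`.
#' @export
simulate_transcription <- function(gene, model = slippage_model(), n = 10000L,
                                   seed = 1L) {
  stopifnot(inherits(model, "slippage_model"))
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be >= 1", call. = FALSE)
  x <- gene$cds
  run <- as.list(gene$run[1L, ])
  stop_start <- gene$premature_stop
  ks <- withr::with_seed(seed,
    sample(model$k, n, replace = TRUE, prob = model$p))
  kc <- table(factor(ks, levels = model$k))
  seen <- model$k[kc > 0L]
  per_k <- lapply(seen, function(k) {
    ed <- apply_slippage_edit(x, run, k)
    exd <- cds(ed$edited_seq, id = x$id, source = x$source)
    p <- translate_cds(exd)
    tibble::tibble(k = k, a_count = run$length + k, length_aa = p$length_aa,
                   restored = translation_passes(exd, stop_start + k),
                   count = as.integer(kc[as.character(k)]))
  })
  variants <- do.call(rbind, per_k)
  a_counts <- tapply(variants$count, variants$a_count, sum)
  v_counts <- tapply(variants$count, variants$length_aa, sum)
  structure(list(n_transcripts = n,
                 variants = variants,
                 a_count_counts = a_counts,
                 variant_counts = v_counts,
                 true_restoring_fraction =
                   sum(variants$count[variants$restored]) / n,
                 gene_id = x$id,
                 native_run_length = run$length),
            class = "simulated_population")
}

#' Simulate a western-blot readout of a simulated population
#'
#' Pools restored (long) and non-restored (short) variant counts and applies
#' independent multiplicative lognormal noise `exp(N(0, noise_sigma^2))` to
#' each band intensity.
#'
#' @param pop A [simulate_transcription()] result.
#' @param noise_sigma Lognormal sigma of the band-intensity noise.
#' @param seed Seed for the noise draws.
#' @param slippage_product Passed to [band_quant()]; `"long"` for the
#'   restoration architecture the generator designs.
#' @return A [band_quant()].
#' @export
simulate_western <- function(pop, noise_sigma = 0.05, seed = 1L,
                             slippage_product = "long") {
  stopifnot(inherits(pop, "simulated_population"))
  long <- sum(pop$variants$count[pop$variants$restored])
  short <- sum(pop$variants$count[!pop$variants$restored])
  noise <- withr::with_seed(seed, exp(stats::rnorm(2L, 0, noise_sigma)))
  band_quant(pop$gene_id,
             intensity_long = long * noise[1L],
             intensity_short = short * noise[2L],
             slippage_product = slippage_product)
}

#' Simulate the three-construct GFP reporter readout
#'
#' Emulates the reporter scheme: a negative control at background, a +1
#' reporter at `background + true_f * span`, and a frame-restored reference
#' at `background + span`, with independent additive Gaussian noise per
#' replicate. Defaults put the reference ~20-fold over background —
#' qualitatively like the real reporter, in arbitrary units.
#'
#' @param true_f True +1 frameshift frequency in \[0, 1\].
#' @param f_max_scale Span between background and the 100% reference (A.U.).
#' @param noise_sigma Per-replicate Gaussian noise sd, as a fraction of the
#'   span.
#' @param replicates Number of replicates per construct.
#' @param seed Seed for the noise draws.
#' @param background Background fluorescence (A.U.).
#' @return A [reporter_set()].
#' @export
simulate_reporters <- function(true_f, f_max_scale = 2000, noise_sigma = 0.05,
                               replicates = 3L, seed = 1L, background = 100) {
  if (true_f < 0 || true_f > 1) stop("`true_f` must lie in [0, 1]", call. = FALSE)
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)
  sd_abs <- noise_sigma * f_max_scale
  withr::with_seed(seed, {
    f_neg <- background + stats::rnorm(replicates, 0, sd_abs)
    f_test <- background + true_f * f_max_scale + stats::rnorm(replicates, 0, sd_abs)
    f_max <- background + f_max_scale + stats::rnorm(replicates, 0, sd_abs)
    reporter_set(f_neg = f_neg, f_test = f_test, f_max = f_max)
  })
}
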