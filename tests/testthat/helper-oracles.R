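# Independent oracles, coded without reusing the package's internals.

# position-by-position homopolymer run counter
naive_find_runs <- function(seq, base, min_length) {
  v <- strsplit(chartr("U", "T", toupper(seq)), "")[[1L]]
  out <- data.frame(start = integer(), length = integer())
  i <- 1L
  while (i <= length(v)) {
    if (v[i] == base) {
      j <- i
      while (j < length(v) && v[j + 1L] == base) j <- j + 1L
      if (j - i + 1L >= min_length)
        out <- rbind(out, data.frame(start = i, length = j - i + 1L))
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# translation via seqinr (code 11), residues until first stop
oracle_translate <- function(seq, frame = 0L) {
  s <- chartr("U", "T", toupper(seq))
  aa <- seqinr::translate(seqinr::s2c(s), frame = frame, numcode = 11)
  stop_i <- which(aa == "*")
  if (length(stop_i) > 0L)
    list(residues = paste(aa[seq_len(stop_i[1L] - 1L)], collapse = ""),
         terminated = TRUE)
  else
    list(residues = paste(aa, collapse = ""), terminated = FALSE)
}

# string-surgery slippage edit: resize the run at [start, start+len-1] by k
oracle_edit <- function(seq, run_start, run_len, k) {
  pre <- substr(seq, 1L, run_start - 1L)
  post <- substr(seq, run_start + run_len, nchar(seq))
  paste0(pre, strrep("A", run_len + k), post)
}

# does translating the k-edited transcript pass the premature stop codon?
oracle_restores <- function(seq, run_start, run_len, stop_start, k) {
  ed <- oracle_edit(seq, run_start, run_len, k)
  tr <- oracle_translate(ed)
  end_nt <- 3L * nchar(tr$residues) + if (tr$terminated) 3L else 0L
  end_nt > stop_start + k + 2L
}

# small random slippery-site designs, fast enough for sweeps
random_small_design <- function(seed) {
  withr::with_seed(seed, {
    run_len <- sample(8:12, 1L)
    comp <- (3L - run_len %% 3L) %% 3L
    spacer <- comp + 3L * sample(2:8, 1L)
    gene_design(upstream_codons = sample(5:25, 1L),
                run_length = run_len,
                spacer_nt = spacer,
                plus1_orf_codons = sample(c(0L, 3:12), 1L),
                seed = sample.int(1e6, 1L))
  })
}

SYN56 <- "GCCGGCUAUUAUGAGGCGUUUAAAAAAAAAAAUGGGUCCGGGGCUGAUGCUGUUAG"
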