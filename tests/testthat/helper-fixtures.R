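# Small in-code fixtures shared across tests.

# a precursor row in the internal (0-based half-open) layout:
# pad(8) | 5p arm | loop(15) | 3p arm (rc of 5p with substitutions) | pad(8)
make_precursor <- function(name = "osa-MIR9001", arm5 = NULL,
                           arm_len = 21L, annotate_3p = TRUE,
                           species = "osa", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(arm5)) arm5 <- rand_dna(arm_len)
  arm_len <- nchar(arm5)
  arm3 <- rc(arm5)
  for (p in c(5L, 12L)) {
    b <- substr(arm3, p, p)
    substr(arm3, p, p) <- setdiff(c("A", "C", "G", "T"), b)[1]
  }
  seq <- paste0(rand_dna(8), arm5, rand_dna(15), arm3, rand_dna(8))
  data.frame(name = name, sequence = seq, species = species,
             m5_start = 8L, m5_end = 8L + arm_len,
             m5_name = paste0(sub("MIR", "miR", name), "-5p"),
             m3_start = if (annotate_3p) 8L + arm_len + 15L else NA_integer_,
             m3_end = if (annotate_3p) 8L + 2L * arm_len + 15L else NA_integer_,
             m3_name = if (annotate_3p) {
               paste0(sub("MIR", "miR", name), "-3p")
             } else {
               NA_character_
             },
             stringsAsFactors = FALSE)
}

prec_mature5 <- function(prec) {
  substr(prec$sequence, prec$m5_start + 1L, prec$m5_end)
}

prec_arm3_seq <- function(prec) {
  s0 <- 8L + (prec$m5_end - prec$m5_start) + 15L
  substr(prec$sequence, s0 + 1L, s0 + (prec$m5_end - prec$m5_start))
}

# tag table with given per-library counts
make_tags <- function(seqs, counts) {
  out <- data.frame(sequence = seqs, stringsAsFactors = FALSE)
  for (l in names(counts)) out[[l]] <- counts[[l]]
  out
}

# a shared small synthetic study for pipeline-level tests (built once
# per test run; depth reduced for speed)
synth_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- pollensmrna::synth_config(seed = 101, depth = 5e4,
                                     n_junk = 1500L, n_abundant = 80L)
    ref <- pollensmrna::make_reference(cfg)
    dir <- file.path(tempdir(), "pollensmrna-synth-fixture")
    sim <- pollensmrna::simulate_libraries(cfg, ref, dir)
    paths <- pollensmrna::write_reference(ref, dir)
    cache <<- list(cfg = cfg, ref = ref, sim = sim, paths = paths,
                   dir = dir)
    cache
  }
})
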