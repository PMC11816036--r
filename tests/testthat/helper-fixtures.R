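# Shared fixtures, built in code. Tiny hand-written records keep unit
# tests independent of the generator; generated cohorts exercise scale.

tiny_record <- function(id = "p1", visits = list(c("D001", "D002"), "M001"),
                        label = 0L, onset = NULL) {
  if (label == 1L) visits <- c(visits, list(onset))
  list(patient_id = id, visits = visits, label = as.integer(label),
       onset_target_code = onset,
       index_visit = length(visits) - as.integer(label == 1L))
}

tiny_cohort <- function() {
  structure(list(
    tiny_record("p1", list(c("D001", "D002"), "M001")),
    tiny_record("p2", list("D002", c("M001", "P001", "D001")),
                label = 1L, onset = "C25.0"),
    tiny_record("p3", list(c("P001", "P001"))),
    tiny_record("p4", list("D001", "D002", "M001"),
                label = 1L, onset = "C25.9")
  ), class = "nv_cohort")
}

tiny_vocab <- function() build_vocabulary(tiny_cohort())

# small encoder + cohort used across encoder/head/mlm tests
small_setup <- function(n = 30L, seed = 7L, max_len = 16L) {
  cfg_g <- generator_config(n_patients = n, vocab_size = 40,
                            visits_per_patient_range = c(2, 5),
                            codes_per_visit_range = c(1, 4), seed = seed)
  cohort <- generate_cohort(cfg_g)
  vocab <- build_vocabulary(cohort)
  enc <- encoder_config(embedding_dim = 12L, n_layers = 2L, n_heads = 2L,
                        feedforward_dim = 20L, max_visits = 8L,
                        max_len = max_len, seed = seed)
  list(gen = cfg_g, cohort = cohort, vocab = vocab, enc = enc,
       weights = init_encoder_weights(enc, vocab))
}
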