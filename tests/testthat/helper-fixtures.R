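# Shared fixtures: the introductory example pair (significant original
# t(78) = 2.211 with n = 40/40; replication t(158) = 1.040 with n = 80/80)
# and a correlation-scale pair for the normal backend.

example_original <- function() g_from_t(2.211, 40, 40)
example_replication <- function() g_from_t(1.040, 80, 80)

example_pair <- function(...) {
  study_pair(example_original(), example_replication(), ...)
}

correlation_pair <- function(r_o = 0.45, n_o = 31, r_r = 0.10, n_r = 55) {
  study_pair(z_from_r(r_o, n_o), z_from_r(r_r, n_r), backend = "normal")
}
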