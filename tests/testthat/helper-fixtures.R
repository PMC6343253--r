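# Small simulated-trial builders shared across test files.

# A compact NB trial: two arms, four 4-weekly visits, EM-like means.
small_nb_config <- function(seed, n_per_arm = c(150, 150),
                            alpha_report = 0.2397, frr = 0.761,
                            bound_counts = FALSE) {
  simulation_config("EM", n_per_arm, c(0, 4, 8, 12),
                    c(8.261, 7.199, 6.731, 6.4337), frr, "frr", "negbin",
                    alpha_report = alpha_report,
                    bound_counts = bound_counts, seed = seed)
}

small_bb_config <- function(seed, n_per_arm = c(150, 150), rho = 0.0297) {
  simulation_config("EM", n_per_arm, c(0, 4, 8, 12),
                    c(7.945, 7.080, 6.672, 6.386), -0.327, "logit", "betabin",
                    rho = rho, seed = seed)
}

# Hand-written 10-row fixture used for log-likelihood product oracles.
fixture10 <- function() {
  mmd_dataset(data.frame(
    subject_id = rep(c("p1", "p2", "p3", "p4", "p5"), each = 2),
    visit_week = rep(c(0, 4), 5),
    arm = rep(c(0, 0, 1, 1, 0), each = 2),
    mmd = c(5, 3, 9, 7, 0, 2, 12, 6, 8, 8)))
}
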