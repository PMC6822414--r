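# shared fixtures, all built in code

pilot_attrs <- function() {
  read_attribute_config(system.file("extdata", "pilot_table9.dcf",
                                    package = "capdce"))
}

final_attrs <- function() {
  read_attribute_config(system.file("extdata", "final_table12.dcf",
                                    package = "capdce"))
}

# minimal 2-attribute set without opt-out: a in {0,1}, b in {0,2}
toy_attrs <- function(optout = FALSE) {
  dce_attribute_set(list(
    dce_attribute("a", codes = c(0, 1), labels = c("a0", "a1"),
                  sign = "positive", prior = 0.5),
    dce_attribute("b", codes = c(0, 2), labels = c("b0", "b1"),
                  sign = "negative", prior = -0.25)),
    optout_asc = optout, name = "toy")
}

# the fixed toy design the frozen oracles refer to:
# task 1: (a0,b0) vs (a1,b1); task 2: (a0,b1) vs (a1,b0)
toy_design <- function() {
  dce_design(list(rbind(c(1L, 1L), c(2L, 2L)),
                  rbind(c(1L, 2L), c(2L, 1L))),
             toy_attrs(), optout = FALSE)
}

# Table 10 printed coefficients (rounded), utility-parameter order
table10_beta <- function() {
  c(schedule = -0.0895, timeliness = 0.4808, rate = 0.0003,
    services = -0.0360, performance = 0.0540, optout = -0.2319)
}

# random designs of a given shape, for D-error baselines
random_designs <- function(attrs, n_tasks, n_alts, n_designs, seed) {
  cand <- full_candidate_set(attrs)
  set.seed(seed)
  lapply(seq_len(n_designs), function(i) {
    tasks <- lapply(seq_len(n_tasks), function(s)
      cand[sample.int(nrow(cand), n_alts), , drop = FALSE])
    dce_design(tasks, attrs)
  })
}
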