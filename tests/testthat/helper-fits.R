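# Shared fitted models, computed lazily and cached so several test files
# can reuse the same (expensive) MCMC runs.

.fit_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fit_cache))
    assign(name, force(expr), envir = .fit_cache)
  get(name, envir = .fit_cache)
}

# continuous study-condition fixture: generator defaults (n = 500, M = 7,
# 5 active exposures), 2000 iterations
continuous_fixture <- function() {
  cached("continuous_sim", kmr_sim_continuous(seed = 101))
}

continuous_fit <- function() {
  cached("continuous_fit",
         kmreg(continuous_fixture()$data,
               control = kmr_control(n_iter = 2000, seed = 101)))
}

# binary study-condition fixture: generator defaults (n = 200, M = 30,
# 4 active exposures), 2000 iterations
binary_fixture <- function() {
  cached("binary_sim", kmr_sim_binary(seed = 202))
}

binary_fit <- function() {
  cached("binary_fit",
         kmreg(binary_fixture()$data,
               control = kmr_control(n_iter = 2000, seed = 202)))
}

# small additive fixture for the summary-layer tests: linear truth in
# z1 (+) and z2 (-), z3 inert
additive_fixture <- function() {
  cached("additive_sim",
         kmr_sim_continuous(
           n = 150, M = 3, rho = 0.3,
           terms = list(list(type = "linear", var = 1, a = 1),
                        list(type = "linear", var = 2, a = -0.7)),
           beta = 1, sd = 0.5, seed = 11))
}

additive_fit <- function() {
  cached("additive_fit",
         kmreg(additive_fixture()$data,
               control = kmr_control(n_iter = 1500, seed = 11)))
}
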