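# Shared fixtures: the packaged network and reference individual are
# immutable in tests, so build them once per test run.

the_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- clopidogrel_network()
    m
  }
})

the_individual <- local({
  i <- NULL
  function() {
    if (is.null(i)) i <<- build_reference_individual()
    i
  }
})

# sparse clinical-style sampling grid (h)
SPARSE_TIMES <- c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12, 24)

# classical RK4 on a scalar ODE; independent oracle for pool dynamics
rk4_scalar <- function(deriv, y0, t_end, dt) {
  y <- y0
  t <- 0
  while (t < t_end - 1e-12) {
    h <- min(dt, t_end - t)
    k1 <- deriv(y)
    k2 <- deriv(y + h / 2 * k1)
    k3 <- deriv(y + h / 2 * k2)
    k4 <- deriv(y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
  }
  y
}

# set every rate parameter of the network to zero (inert test compound set)
zero_rate_model <- function(model = the_model()) {
  for (i in seq_along(model$processes)) model$processes[[i]]$kcat_per_min <- 0
  for (i in seq_along(model$clearances)) model$clearances[[i]]$cl_L_per_h <- 0
  model$interactions <- list()
  model
}

# minimal one-compound model with a single linear renal clearance, low
# extraction, for closed-form pharmacokinetic checks
one_compartment_model <- function(cl_unbound_L_per_h = 50, fu = 0.01,
                                  kp = 0.02) {
  cp <- compound("testdrug", 300, fu = fu, kp = kp, ka_per_h = 2)
  model_definition(list(cp),
                   clearances = list(clearance_process(
                     "testdrug", "renal", cl_unbound_L_per_h)))
}
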