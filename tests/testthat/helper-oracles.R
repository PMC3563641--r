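# Independent second transcriptions of the registry models, written in
# stoichiometry-matrix form (reactions x species) rather than per-species
# balance equations. Used only as oracles against the package rhs functions.

oracle_simple_enzyme <- function(state, p) {
  # species order: S, E, ES, P; reactions: bind, unbind, catalyze
  N <- rbind(bind = c(-1, -1, 1, 0),
             unbind = c(1, 1, -1, 0),
             cat = c(0, 1, -1, 1))
  v <- c(bind = p[["k1"]] * state[1] * state[2],
         unbind = p[["km1"]] * state[3],
         cat = p[["k2"]] * state[3])
  as.vector(t(N) %*% v)
}

oracle_hysteretic_enzyme <- function(state, p) {
  # species order: S, Ei, Ea, EiS, EaS, P
  # reactions: bind_i, unbind_i, cat_i, act_free, deact_free, bind_a,
  #            unbind_a, act_cplx, deact_cplx, cat_a
  # each binding consumes three substrate molecules; catalysis yields one
  # product from a complex carrying three substrates
  N <- rbind(
    bind_i     = c(-3, -1, 0, 1, 0, 0),
    unbind_i   = c(3, 1, 0, -1, 0, 0),
    cat_i      = c(0, 1, 0, -1, 0, 1),
    act_free   = c(0, -1, 1, 0, 0, 0),
    deact_free = c(0, 1, -1, 0, 0, 0),
    bind_a     = c(-3, 0, -1, 0, 1, 0),
    unbind_a   = c(3, 0, 1, 0, -1, 0),
    act_cplx   = c(0, 0, 0, -1, 1, 0),
    deact_cplx = c(0, 0, 0, 1, -1, 0),
    cat_a      = c(0, 0, 1, 0, -1, 1))
  v <- c(p[["k1"]] * state[2] * state[1],
         p[["k2"]] * state[4],
         p[["k3"]] * state[4],
         p[["k4"]] * state[2],
         p[["k5"]] * state[3],
         p[["k6"]] * state[3] * state[1],
         p[["k7"]] * state[5],
         p[["k8"]] * state[4],
         p[["k9"]] * state[5],
         p[["k10"]] * state[5])
  as.vector(t(N) %*% v)
}

oracle_benchmark <- function(state, p, u, variant = "correct") {
  B <- state[1]; S <- state[2]; M1 <- state[3]; M2 <- state[4]; E <- state[5]
  D <- u[["q_in"]]
  r1 <- p[["k1"]] * S / (p[["K1"]] + S)
  inh <- p[["KI"]] / (p[["KI"]] + M2)
  r2 <- p[["k2"]] * E * M1 / (p[["K2"]] + M1) * if (variant == "B") 1 else inh
  r4 <- if (variant == "A") p[["ks"]] else p[["ks"]] * inh
  mu <- p[["Y"]] * r1
  c((mu - D) * B,
    D * (u[["c_in"]] - S) - r1 * B,
    r1 - r2 - mu * M1,
    r2 - p[["k3"]] * M2 / (p[["K3"]] + M2) - mu * M2,
    r4 - (p[["kd"]] + mu) * E)
}

# small helper models used across test files ---------------------------------

decay_model <- function() {
  kinetic_model(name = "decay", species = "S", parameters = "k",
                rhs = function(t, x, p, u) -p[["k"]] * x[1],
                conservation = list())
}

constant_model <- function(n = 2) {
  kinetic_model(name = "constant", species = paste0("x", seq_len(n)),
                parameters = "dummy",
                rhs = function(t, x, p, u) rep(0, length(x)))
}

# linear response model y(t) = theta * S0 * t, as an explicit ODE
linear_gain_model <- function(name, gain) {
  force(gain)
  kinetic_model(name = name, species = "y", parameters = "theta",
                rhs = function(t, x, p, u) gain * p[["theta"]])
}

uniform_design <- function(n, dt, x0) {
  experimental_design(intervals = rep(dt, n), x0 = x0)
}

wide_steps <- function() {
  # step configs whose weights are ~1 everywhere they are evaluated in tests
  list(dt = step_config(width = 1e-3, center = -1, steepness = 10),
       p = step_config(width = 1e-3, center = 1e6, steepness = 10))
}
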