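#' Define a kinetic ODE model
#'
#' A `kinetic_model` bundles everything the simulator and the design
#' machinery need to know about one rival hypothesis: the ordered species
#' labels, the ordered parameter labels, the right-hand-side function, the
#' measurable (observed) species, any external-input slots, and a list of
#' linear conservation relations used for numerical self-checks.
#'
#' @param name Identifier of the model.
#' @param species Character vector of species labels (state ordering).
#' @param parameters Character vector of parameter labels.
#' @param rhs Function `(t, state, params, inputs)` returning the derivative
#'   vector, same length and order as `species`. `params` and `inputs` are
#'   named numeric vectors.
#' @param observed Character vector, subset of `species`, the measurable
#'   species. Defaults to all species.
#' @param inputs Character vector of external-input labels (may be empty).
#' @param conservation List of named numeric vectors; each gives coefficients
#'   of a linear combination of species that the dynamics hold constant.
#'
#' @return An object of class `kinetic_model`.
#' @export
kinetic_model <- function(name, species, parameters, rhs,
                          observed = species, inputs = character(),
                          conservation = list()) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(species), length(species) >= 1L,
            is.character(parameters), is.function(rhs))
  if (!all(observed %in% species))
    stop("observed species must be a subset of the model species")
  for (cc in conservation) {
    if (is.null(names(cc)) || !all(names(cc) %in% species))
      stop("conservation coefficients must be named by species")
  }
  structure(list(name = name, species = species, parameters = parameters,
                 rhs = rhs, observed = observed, inputs = inputs,
                 conservation = conservation),
            class = "kinetic_model")
}

#' @export
print.kinetic_model <- function(x, ...) {
  cat("Kinetic model:", x$name, "\n")
  cat("  species   :", paste(x$species, collapse = ", "), "\n")
  cat("  parameters:", paste(x$parameters, collapse = ", "), "\n")
  cat("  observed  :", paste(x$observed, collapse = ", "), "\n")
  if (length(x$inputs))
    cat("  inputs    :", paste(x$inputs, collapse = ", "), "\n")
  cat("  conservation relations:", length(x$conservation), "\n")
  invisible(x)
}

#' Evaluate a model right-hand side with dimension checks
#'
#' @param model A [kinetic_model()].
#' @param state Numeric state vector (order of `model$species`).
#' @param params Named numeric parameter vector.
#' @param inputs Named numeric vector of current external-input values.
#' @param t Time (passed through to the rhs; most registry models are
#'   autonomous).
#' @return Derivative vector, length `length(model$species)`.
#' @export
eval_rhs <- function(model, state, params, inputs = numeric(), t = 0) {
  if (length(state) != length(model$species))
    stop(sprintf("state has length %d but model '%s' has %d species",
                 length(state), model$name, length(model$species)))
  params <- check_params(model, params)
  dx <- model$rhs(t, state, params, inputs)
  if (length(dx) != length(model$species))
    stop("rhs returned a vector of the wrong length")
  unname(dx)
}

check_params <- function(model, params) {
  if (is.null(names(params))) {
    if (length(params) != length(model$parameters))
      stop("unnamed parameter vector of wrong length")
    names(params) <- model$parameters
  }
  missing <- setdiff(model$parameters, names(params))
  if (length(missing))
    stop("missing parameters: ", paste(missing, collapse = ", "))
  if (any(!is.finite(params[model$parameters])))
    stop("parameters must be finite")
  out <- params[model$parameters]
  storage.mode(out) <- "double"
  out
}

## ---------------------------------------------------------------------------
## Registry models
## ---------------------------------------------------------------------------

# Simple Michaelis-Menten mechanism S + E <=> ES -> E + P, mass action.
rhs_simple_enzyme_fn <- function(t, x, p, u) {
  S <- x[1]; E <- x[2]; ES <- x[3]
  v1 <- p[["k1"]] * S * E      # association
  v2 <- p[["km1"]] * ES        # dissociation
  v3 <- p[["k2"]] * ES         # catalysis
  c(-v1 + v2,                  # dS
    -v1 + v2 + v3,             # dE
    v1 - v2 - v3,              # dES
    v3)                        # dP
}

#' Right-hand side of the simple enzyme model
#'
#' Mass-action kinetics of the mechanism S + E <=> ES -> E + P with
#' association rate `k1`, dissociation rate `km1` (the constant usually
#' written k_-1) and catalytic rate `k2`. Total enzyme (E + ES) and total
#' substrate material (S + ES + P) are conserved.
#'
#' @param state Numeric 4-vector (S, E, ES, P).
#' @param params Named numeric vector with `k1`, `km1`, `k2`.
#' @return Derivative 4-vector.
#' @export
rhs_simple_enzyme <- function(state, params) {
  eval_rhs(get_model("simple_enzyme"), state, params)
}

# Slow-transition (hysteretic) mechanism: the enzyme exists in an inactive
# conformation Ei and an active conformation Ea. Both bind three substrate
# molecules, forming complexes EiS and EaS that each carry 3 S, and each
# catalytic event releases one product molecule (3 S -> 1 P). The binding
# rates are formal kinetic laws first order in S; the stoichiometric factor
# 3 appears in dS/dt. Rate constants:
#   k1/k2: Ei + 3S <=> EiS     k3 : EiS -> Ei + P
#   k4/k5: Ei <=> Ea (slow conformational transition of the free enzyme)
#   k6/k7: Ea + 3S <=> EaS     k10: EaS -> Ea + P
#   k8/k9: EiS <=> EaS (transition of the complexed enzyme)
rhs_hysteretic_enzyme_fn <- function(t, x, p, u) {
  S <- x[1]; Ei <- x[2]; Ea <- x[3]; EiS <- x[4]; EaS <- x[5]
  b_i  <- p[["k1"]] * Ei * S    # inactive binding
  d_i  <- p[["k2"]] * EiS       # inactive dissociation
  c_i  <- p[["k3"]] * EiS       # inactive catalysis
  t_f  <- p[["k4"]] * Ei        # Ei -> Ea
  t_r  <- p[["k5"]] * Ea        # Ea -> Ei
  b_a  <- p[["k6"]] * Ea * S    # active binding
  d_a  <- p[["k7"]] * EaS       # active dissociation
  t_cf <- p[["k8"]] * EiS       # EiS -> EaS
  t_cr <- p[["k9"]] * EaS       # EaS -> EiS
  c_a  <- p[["k10"]] * EaS      # active catalysis
  c(3 * (-b_i + d_i - b_a + d_a),            # dS  (3 substrate per event)
    -b_i + d_i + c_i - t_f + t_r,            # dEi
    -b_a + d_a + c_a + t_f - t_r,            # dEa
    b_i - d_i - c_i - t_cf + t_cr,           # dEiS
    b_a - d_a - c_a + t_cf - t_cr,           # dEaS
    c_i + c_a)                               # dP
}

#' Right-hand side of the hysteretic (slow transition) enzyme model
#'
#' Two-conformation mechanism of a monomeric hysteretic enzyme: an inactive
#' form Ei and an active form Ea interconvert slowly (k4/k5 free, k8/k9
#' complexed); both bind three substrate molecules (k1/k2 inactive, k6/k7
#' active) and catalyze product formation (k3 inactive, k10 active). Three
#' substrate molecules form one product molecule. Total enzyme
#' (Ei + Ea + EiS + EaS) and total substrate material (S + 3 EiS + 3 EaS +
#' 3 P) are conserved. When the active catalytic rate k10 greatly exceeds k3
#' and the conformational transitions are slow, substrate and product curves
#' are sigmoidal.
#'
#' @param state Numeric 6-vector (S, Ei, Ea, EiS, EaS, P).
#' @param params Named numeric vector with `k1` ... `k10`.
#' @return Derivative 6-vector.
#' @export
rhs_hysteretic_enzyme <- function(state, params) {
  eval_rhs(get_model("hysteretic_enzyme"), state, params)
}

# Chemostat benchmark network of a fictitious organism (5 states). Rates:
#   r1 = k1 * S/(K1+S)                     substrate uptake (per biomass)
#   r2 = k2 * E * M1/(K2+M1) * KI/(KI+M2)  enzymatic M1 -> M2 conversion,
#                                          non-competitively inhibited by M2
#   r3 = k3 * M2/(K3+M2)                   M2 consumption
#   r4 = ks * KI/(KI+M2)                   enzyme synthesis, repressed by M2
#   r5 = Y * r1                            specific growth from partial uptake
# Variant A: r4 = ks (constant synthesis velocity).
# Variant B: the inhibition fraction of r2 is omitted.
make_rhs_benchmark <- function(variant) {
  force(variant)
  function(t, x, p, u) {
    B <- x[1]; S <- x[2]; M1 <- x[3]; M2 <- x[4]; E <- x[5]
    q_in <- u[["q_in"]]; q_out <- u[["q_out"]]; c_in <- u[["c_in"]]
    V <- 1  # flow rates in and out are equal, so reactor volume is constant
    D <- q_in / V
    if (any(c(p[["K1"]], p[["K2"]], p[["K3"]], p[["KI"]]) < 0))
      stop("Michaelis and inhibition constants must be nonnegative")
    r1 <- p[["k1"]] * S / (p[["K1"]] + S)
    inhib <- p[["KI"]] / (p[["KI"]] + M2)
    r2 <- p[["k2"]] * E * M1 / (p[["K2"]] + M1) *
      (if (variant == "B") 1 else inhib)
    r3 <- p[["k3"]] * M2 / (p[["K3"]] + M2)
    r4 <- if (variant == "A") p[["ks"]] else p[["ks"]] * inhib
    mu <- p[["Y"]] * r1
    c((mu - D) * B,                       # biomass
      D * (c_in - S) - r1 * B,            # tank substrate
      r1 - r2 - mu * M1,                  # M1
      r2 - r3 - mu * M2,                  # M2
      r4 - (p[["kd"]] + mu) * E)          # enzyme
  }
}

#' Right-hand side of the bioreactor benchmark network
#'
#' Chemostat model of a fictitious organism: biomass B grows on tank
#' substrate S; internal metabolite M1 is synthesized from the uptake flux
#' and converted to M2 by the enzyme E, whose synthesis and activity are both
#' regulated by M2. External inputs are the (equal) flow rates `q_in`,
#' `q_out` and the feed substrate concentration `c_in`. The `correct` variant
#' carries both regulations; variant `A` replaces the enzyme-synthesis rate
#' by a constant; variant `B` omits the non-competitive inhibition fraction
#' of the conversion rate.
#'
#' @param state Numeric 5-vector (B, S, M1, M2, E).
#' @param params Named numeric vector with k1, K1, Y, k2, K2, KI, k3, K3, ks, kd.
#' @param inputs Named numeric vector with `q_in`, `q_out`, `c_in`.
#' @param variant One of "correct", "A", "B".
#' @return Derivative 5-vector.
#' @export
rhs_benchmark <- function(state, params, inputs, variant = c("correct", "A", "B")) {
  variant <- match.arg(variant)
  eval_rhs(get_model(paste0("benchmark_", variant)), state, params, inputs)
}

#' Reference parameter sets for the registry models
#'
#' `hysteretic_true_params()` returns the ten rate constants of the hysteretic
#' enzyme model used throughout for synthetic data generation;
#' `benchmark_known_params()` returns the nominal parameter set of the correct
#' benchmark model (six constants treated as known plus nominal values for the
#' estimated ones).
#'
#' @return Named numeric vector.
#' @export
hysteretic_true_params <- function() {
  c(k1 = 0.05, k2 = 0.001, k3 = 0.06, k4 = 0.001, k5 = 0.001,
    k6 = 6.0, k7 = 0.001, k8 = 0.001, k9 = 0.01, k10 = 4.0)
}

#' @rdname hysteretic_true_params
#' @export
benchmark_known_params <- function() {
  c(k1 = 7.0e-5, K1 = 342.3e-6, Y = 0.4437, k2 = 6.0e6, K2 = 2.4e4,
    KI = 3.0e6, k3 = 12.2, K3 = 10.0, ks = 0.166, kd = 8.2e-3)
}

the_registry <- new.env(parent = emptyenv())

#' Register a model or fetch one from the registry
#'
#' The built-in registry holds the simple and hysteretic enzyme models and the
#' three benchmark variants. `register_model()` lets user code add rival
#' model pairs under new names; `get_model()` retrieves them; `list_models()`
#' names all registered models.
#'
#' @param model A [kinetic_model()].
#' @param name Registry name.
#' @return `get_model()` returns the `kinetic_model`; `register_model()`
#'   returns it invisibly; `list_models()` a character vector.
#' @export
register_model <- function(model) {
  stopifnot(inherits(model, "kinetic_model"))
  assign(model$name, model, envir = the_registry)
  invisible(model)
}

#' @rdname register_model
#' @export
get_model <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE))
    stop(sprintf("unknown model '%s'; registered: %s", name,
                 paste(list_models(), collapse = ", ")))
  get(name, envir = the_registry, inherits = FALSE)
}

#' @rdname register_model
#' @export
list_models <- function() sort(ls(the_registry))

register_builtin_models <- function() {
  register_model(kinetic_model(
    name = "simple_enzyme",
    species = c("S", "E", "ES", "P"),
    parameters = c("k1", "km1", "k2"),
    rhs = function(t, x, p, u) rhs_simple_enzyme_fn(t, x, p, u),
    observed = c("S", "P"),
    conservation = list(c(E = 1, ES = 1), c(S = 1, ES = 1, P = 1))))

  register_model(kinetic_model(
    name = "hysteretic_enzyme",
    species = c("S", "Ei", "Ea", "EiS", "EaS", "P"),
    parameters = paste0("k", 1:10),
    rhs = function(t, x, p, u) rhs_hysteretic_enzyme_fn(t, x, p, u),
    observed = c("S", "P"),
    conservation = list(c(Ei = 1, Ea = 1, EiS = 1, EaS = 1),
                        c(S = 1, EiS = 3, EaS = 3, P = 3))))

  bench_species <- c("B", "S", "M1", "M2", "E")
  bench_params <- c("k1", "K1", "Y", "k2", "K2", "KI", "k3", "K3", "ks", "kd")
  for (v in c("correct", "A", "B")) {
    register_model(kinetic_model(
      name = paste0("benchmark_", v),
      species = bench_species,
      parameters = bench_params,
      rhs = make_rhs_benchmark(v),
      observed = bench_species,
      inputs = c("q_in", "q_out", "c_in")))
  }
}

#' Numerically check the conservation relations of a model
#'
#' Evaluates the time derivative of every declared conserved linear
#' combination at random states and parameters and returns the largest
#' relative violation.
#'
#' @param model A [kinetic_model()].
#' @param params Named parameter vector; random positive values if missing.
#' @param n Number of random states.
#' @param seed RNG seed.
#' @param inputs Named input values (defaults to 1 for every input).
#' @return Maximum relative |d(combination)/dt| over all checks.
#' @export
check_conservation <- function(model, params = NULL, n = 100, seed = 1,
                               inputs = NULL) {
  if (!length(model$conservation)) return(0)
  set.seed(seed)
  if (is.null(inputs))
    inputs <- stats::setNames(rep(1, length(model$inputs)), model$inputs)
  worst <- 0
  for (i in seq_len(n)) {
    x <- stats::runif(length(model$species), 0, 10)
    p <- if (is.null(params))
      stats::setNames(stats::runif(length(model$parameters), 0, 5),
                      model$parameters) else params
    dx <- eval_rhs(model, x, p, inputs)
    scale <- max(1, max(abs(dx)))
    for (cc in model$conservation) {
      coef <- stats::setNames(rep(0, length(model$species)), model$species)
      coef[names(cc)] <- cc
      worst <- max(worst, abs(sum(coef * dx)) / scale)
    }
  }
  worst
}
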