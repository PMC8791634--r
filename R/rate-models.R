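#' Rate models for binary-trait evolution
#'
#' A rate model maps named, non-negative rate parameters onto the off-diagonal
#' entries of a continuous-time Markov rate matrix over a small state space.
#' Entries not claimed by any parameter are structural zeros; in all
#' two-character models the "dual" transitions (both characters changing in
#' one instant) are structural zeros, as is standard for correlated-evolution
#' discrete models.
#'
#' Two-character state labels are two digits: the first digit is the focal
#' trait, the second the companion character (the other cleavage site, or a
#' habitat-like character such as terrestrial status or lungs).
#'
#' @param id model identifier.
#' @param states character vector of state labels.
#' @param params character vector of parameter names.
#' @param edges data frame with columns `from`, `to` (state labels) and
#'   `param` (parameter name); every listed entry receives that parameter.
#' @param nests ids of models this model nests (for likelihood-ratio tests).
#' @return an object of class `rate_model`.
#' @export
rate_model <- function(id, states, params, edges, nests = character(0)) {
  ns <- length(states)
  index <- matrix(0L, ns, ns, dimnames = list(states, states))
  for (i in seq_len(nrow(edges))) {
    f <- edges$from[i]; t <- edges$to[i]
    if (f == t) stop("diagonal entries cannot carry parameters")
    k <- match(edges$param[i], params)
    if (is.na(k)) stop("unknown parameter: ", edges$param[i])
    index[f, t] <- k
  }
  structure(list(id = id, states = states, params = params,
                 index = index, nests = nests),
            class = "rate_model")
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model '", x$id, "': ", length(x$states), " states, parameters ",
      paste(x$params, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Single binary trait model (gain/loss)
#'
#' @param equal_rates use a single rate for gain and loss.
#' @return a [rate_model()] on states `0`, `1`.
#' @export
model_single_trait <- function(equal_rates = FALSE) {
  if (equal_rates) {
    rate_model("single_trait_er", c("0", "1"), "rate",
               data.frame(from = c("0", "1"), to = c("1", "0"),
                          param = "rate"))
  } else {
    rate_model("single_trait", c("0", "1"), c("gain", "loss"),
               data.frame(from = c("0", "1"), to = c("1", "0"),
                          param = c("gain", "loss")),
               nests = "single_trait_er")
  }
}

#' Joint state labels for two binary characters
#' @return `c("00", "01", "10", "11")`: first digit trait one, second trait two.
#' @export
pair_states <- function() c("00", "01", "10", "11")

#' Independent model for two coevolving sites
#'
#' Two parameters: one appearance rate and one loss rate shared by both
#' characters, with neither depending on the state of the other character.
#' This is the null model for the site-1/site-2 coevolution test.
#' @return a [rate_model()] on states `00`, `01`, `10`, `11`.
#' @export
model_independent_pair <- function() {
  rate_model(
    "independent_pair", pair_states(), c("gain", "loss"),
    data.frame(
      from  = c("00", "00", "01", "10", "01", "10", "11", "11"),
      to    = c("01", "10", "11", "11", "00", "00", "01", "10"),
      param = c(rep("gain", 4), rep("loss", 4))
    )
  )
}

#' Dependent model for two coevolving sites
#'
#' Adds two free parameters to [model_independent_pair()]: gain and loss rates
#' each split by whether the other character is currently absent or present.
#' @return a [rate_model()].
#' @export
model_dependent_pair <- function() {
  rate_model(
    "dependent_pair", pair_states(),
    c("gain_other_absent", "gain_other_present",
      "loss_other_absent", "loss_other_present"),
    data.frame(
      from  = c("00", "00", "01", "10", "01", "10", "11", "11"),
      to    = c("01", "10", "11", "11", "00", "00", "01", "10"),
      param = c("gain_other_absent", "gain_other_absent",
                "gain_other_present", "gain_other_present",
                "loss_other_absent", "loss_other_absent",
                "loss_other_present", "loss_other_present")
    ),
    nests = "independent_pair"
  )
}

#' Independent model for a trait evolving alongside a one-way character
#'
#' Three parameters: trait gain, trait loss, and the gain rate of the
#' companion character (marine-to-terrestrial transition, or appearance of
#' lungs).  The reverse companion transition is a structural zero, and trait
#' rates do not depend on the companion state: this is the null model for
#' trait-versus-habitat coevolution tests.  State labels: first digit the
#' trait, second digit the companion character.
#' @return a [rate_model()].
#' @export
model_independent_habitat <- function() {
  rate_model(
    "independent_habitat", pair_states(),
    c("gain", "loss", "habitat_gain"),
    data.frame(
      from  = c("00", "01", "10", "11", "00", "10"),
      to    = c("10", "11", "00", "01", "01", "11"),
      param = c("gain", "gain", "loss", "loss",
                "habitat_gain", "habitat_gain")
    )
  )
}

#' Dependent model for a trait evolving alongside a one-way character
#'
#' Adds two free parameters to [model_independent_habitat()]: the trait's gain
#' and loss rates are split between the two companion states (for example
#' marine versus terrestrial).
#' @return a [rate_model()].
#' @export
model_dependent_habitat <- function() {
  rate_model(
    "dependent_habitat", pair_states(),
    c("gain_aquatic", "gain_terrestrial",
      "loss_aquatic", "loss_terrestrial", "habitat_gain"),
    data.frame(
      from  = c("00", "01", "10", "11", "00", "10"),
      to    = c("10", "11", "00", "01", "01", "11"),
      param = c("gain_aquatic", "gain_terrestrial",
                "loss_aquatic", "loss_terrestrial",
                "habitat_gain", "habitat_gain")
    ),
    nests = "independent_habitat"
  )
}

#' Build a rate matrix from a model and parameter values
#'
#' @param model a [rate_model()].
#' @param params named (or model-ordered) numeric vector of non-negative
#'   rates.
#' @return a square rate matrix: off-diagonals carry the mapped parameters,
#'   structural zeros are exactly zero, rows sum to zero.
#' @export
build_rate_matrix <- function(model, params) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.null(names(params))) {
    missing <- setdiff(model$params, names(params))
    if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
    params <- params[model$params]
  }
  if (length(params) != length(model$params))
    stop("expected ", length(model$params), " parameters")
  if (any(!is.finite(params)) || any(params < 0))
    stop("rates must be finite and >= 0")
  ns <- length(model$states)
  Q <- matrix(0, ns, ns, dimnames = list(model$states, model$states))
  pos <- model$index > 0L
  Q[pos] <- params[model$index[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Matrix exponential by scaling-and-squaring with Pade approximation (via
#' [Matrix::expm()]); tiny negative entries from roundoff are clamped to zero
#' and rows renormalized.
#'
#' @param Q a rate matrix.
#' @param t branch length, `>= 0`.
#' @return a stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  P <- as.matrix(Matrix::expm(Q * t))
  P[P < 0] <- 0
  P / rowSums(P)
}
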