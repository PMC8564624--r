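#' Demographic models in diffusion units
#'
#' Constructs a demographic model for one, two or three populations. All
#' quantities are in the dimensionless units of SFS diffusion theory:
#' population sizes as ratios \eqn{\nu = N/N_{ref}} of a reference diploid
#' size, times in units of \eqn{2 N_{ref}} generations, and migration rates
#' as \eqn{M_{ij} = 2 N_{ref} m_{ij}}, where \eqn{m_{ij}} is the fraction of
#' population *i* made up of new migrants from population *j* each
#' generation.
#'
#' Three model families are supported:
#' \describe{
#'   \item{`one_pop_sizechange`}{A single population of relative size
#'     `nu_anc` for the most recent `t_anc` time units, size 1 before that.
#'     With `nu_anc = 1` or `t_anc = 0` this is the equilibrium model.}
#'   \item{`two_pop_sizechange_split_mig`}{An ancestral population changes
#'     size to `nu_anc`, persists for `t_anc`, then splits `t_split` time
#'     units before the present into daughters of sizes `nu1`, `nu2`
#'     exchanging migrants at rates `m12` (into 1 from 2) and `m21`.}
#'   \item{`three_pop_two_splits_mig`}{As above, but the second daughter
#'     (size `nu23`) itself splits at `t_split2 < t_split` into populations
#'     2 and 3 (sizes `nu2`, `nu3`). Migration `m1a`/`ma1` acts between
#'     population 1 and the 2-3 ancestor, and the pairwise rates `m12`,
#'     `m21`, `m13`, `m31`, `m23`, `m32` act among the extant triple.}
#' }
#'
#' @param model_id one of `"one_pop_sizechange"`,
#'   `"two_pop_sizechange_split_mig"`, `"three_pop_two_splits_mig"`.
#' @param params named numeric vector of model parameters (see Details);
#'   omitted parameters take defaults of 1 for sizes and 0 for times and
#'   migration rates.
#' @param N_ref reference diploid population size in individuals, used only
#'   when simulating or converting to real units.
#' @return an object of class `demographic_model`.
#' @seealso [two_pop_model()], [three_pop_model()], [expected_sfs()],
#'   [simulate_coalescent()]
#' @export
demographic_model <- function(model_id, params = numeric(), N_ref = 1e4) {
  model_id <- match.arg(model_id, c(
    "one_pop_sizechange",
    "two_pop_sizechange_split_mig",
    "three_pop_two_splits_mig"
  ))
  spec <- model_param_spec(model_id)
  full <- spec$defaults
  if (length(params)) {
    if (is.null(names(params)) || any(!nzchar(names(params)))) {
      stop("'params' must be a named numeric vector")
    }
    unknown <- setdiff(names(params), names(full))
    if (length(unknown)) {
      stop("unknown parameter(s) for ", model_id, ": ",
           paste(unknown, collapse = ", "))
    }
    full[names(params)] <- params
  }
  if (any(!is.finite(full))) stop("all parameters must be finite")
  if (any(full[spec$sizes] <= 0)) stop("all size ratios must be > 0")
  if (any(full[spec$times] < 0)) stop("all times must be >= 0")
  if (any(full[spec$migs] < 0)) stop("all migration rates must be >= 0")
  if (model_id == "three_pop_two_splits_mig" &&
      full[["t_split2"]] > full[["t_split"]]) {
    stop("'t_split2' must not exceed 't_split' (splits ordered toward present)")
  }
  if (!is.numeric(N_ref) || length(N_ref) != 1L || N_ref <= 0) {
    stop("'N_ref' must be a single positive number")
  }
  structure(
    list(model_id = model_id, params = full, n_pops = spec$n_pops,
         N_ref = N_ref),
    class = "demographic_model"
  )
}

model_param_spec <- function(model_id) {
  switch(model_id,
    one_pop_sizechange = list(
      n_pops = 1L,
      defaults = c(nu_anc = 1, t_anc = 0),
      sizes = "nu_anc", times = "t_anc", migs = character()
    ),
    two_pop_sizechange_split_mig = list(
      n_pops = 2L,
      defaults = c(nu_anc = 1, t_anc = 0, nu1 = 1, nu2 = 1, t_split = 0,
                   m12 = 0, m21 = 0),
      sizes = c("nu_anc", "nu1", "nu2"),
      times = c("t_anc", "t_split"),
      migs = c("m12", "m21")
    ),
    three_pop_two_splits_mig = list(
      n_pops = 3L,
      defaults = c(nu_anc = 1, t_anc = 0, nu1 = 1, nu23 = 1, t_split = 0,
                   nu2 = 1, nu3 = 1, t_split2 = 0, m1a = 0, ma1 = 0,
                   m12 = 0, m21 = 0, m13 = 0, m31 = 0, m23 = 0, m32 = 0),
      sizes = c("nu_anc", "nu1", "nu23", "nu2", "nu3"),
      times = c("t_anc", "t_split", "t_split2"),
      migs = c("m1a", "ma1", "m12", "m21", "m13", "m31", "m23", "m32")
    ),
    stop("unknown model_id: ", model_id)
  )
}

#' @rdname demographic_model
#' @param nu_anc,t_anc,nu1,nu2,t_split,m12,m21 see Details.
#' @export
two_pop_model <- function(nu_anc = 1, t_anc = 0, nu1 = 1, nu2 = 1,
                          t_split = 0, m12 = 0, m21 = 0, N_ref = 1e4) {
  demographic_model("two_pop_sizechange_split_mig",
    c(nu_anc = nu_anc, t_anc = t_anc, nu1 = nu1, nu2 = nu2,
      t_split = t_split, m12 = m12, m21 = m21),
    N_ref = N_ref)
}

#' @rdname demographic_model
#' @param nu23,t_split2,nu3,m1a,ma1,m13,m31,m23,m32 see Details.
#' @export
three_pop_model <- function(nu_anc = 1, t_anc = 0, nu1 = 1, nu23 = 1,
                            t_split = 0, nu2 = 1, nu3 = 1, t_split2 = 0,
                            m1a = 0, ma1 = 0, m12 = 0, m21 = 0, m13 = 0,
                            m31 = 0, m23 = 0, m32 = 0, N_ref = 1e4) {
  demographic_model("three_pop_two_splits_mig",
    c(nu_anc = nu_anc, t_anc = t_anc, nu1 = nu1, nu23 = nu23,
      t_split = t_split, nu2 = nu2, nu3 = nu3, t_split2 = t_split2,
      m1a = m1a, ma1 = ma1, m12 = m12, m21 = m21, m13 = m13, m31 = m31,
      m23 = m23, m32 = m32),
    N_ref = N_ref)
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("<demographic_model>", x$model_id, "\n")
  cat("  populations:", x$n_pops, "  N_ref:", x$N_ref, "\n")
  cat("  parameters (diffusion units):\n")
  print(round(x$params, 6))
  invisible(x)
}

# Epoch decomposition, present -> past. Each epoch: duration (Inf for the
# oldest), nu (per-deme relative sizes), mig (backward per-lineage rates:
# mig[i, j] = M_ij = rate at which an ancestral lineage now in deme i traces
# back to deme j), and map (deme index in the next, older epoch).
demography_epochs <- function(model) {
  p <- as.list(model$params)
  switch(model$model_id,
    one_pop_sizechange = list(
      list(duration = p$t_anc, nu = p$nu_anc, mig = matrix(0, 1, 1), map = 1L),
      list(duration = Inf, nu = 1, mig = matrix(0, 1, 1), map = NULL)
    ),
    two_pop_sizechange_split_mig = list(
      list(duration = p$t_split, nu = c(p$nu1, p$nu2),
           mig = matrix(c(0, p$m21, p$m12, 0), 2, 2), map = c(1L, 1L)),
      list(duration = p$t_anc, nu = p$nu_anc, mig = matrix(0, 1, 1), map = 1L),
      list(duration = Inf, nu = 1, mig = matrix(0, 1, 1), map = NULL)
    ),
    three_pop_two_splits_mig = {
      mig3 <- matrix(0, 3, 3)
      mig3[1, 2] <- p$m12; mig3[2, 1] <- p$m21
      mig3[1, 3] <- p$m13; mig3[3, 1] <- p$m31
      mig3[2, 3] <- p$m23; mig3[3, 2] <- p$m32
      mig2 <- matrix(c(0, p$ma1, p$m1a, 0), 2, 2)
      list(
        list(duration = p$t_split2, nu = c(p$nu1, p$nu2, p$nu3),
             mig = mig3, map = c(1L, 2L, 2L)),
        list(duration = p$t_split - p$t_split2, nu = c(p$nu1, p$nu23),
             mig = mig2, map = c(1L, 1L)),
        list(duration = p$t_anc, nu = p$nu_anc, mig = matrix(0, 1, 1),
             map = 1L),
        list(duration = Inf, nu = 1, mig = matrix(0, 1, 1), map = NULL)
      )
    }
  )
}
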