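# Five-scenario simulation benchmark with planted block cluster structure.
# Each scenario builds two observed datatypes from block prototypes and
# isolates one failure mode of naive integration:
#   sd1 scale conflicts      : one noisy prototype, power vs exponential scale
#   sd2 noise-type conflicts : normal vs uniform noise on a clean prototype
#   sd3 noise-size conflicts : normal noise with two different sds
#   sd4 incomplete structure : each datatype defines only half the patients
#   sd5 conflicting structure: two crossing bipartitions (4 true classes)

.SCENARIOS <- c("sd1", "sd2", "sd3", "sd4", "sd5")

# two complementary 0/1 blocks (class 1: first half of variables, class 2:
# second half), the canonical prototype shared by sd1-sd3
.blockPrototype <- function(nPerBlock, nVars) {
  half <- nVars %/% 2L
  rbind(
    cbind(matrix(1, nPerBlock, half), matrix(0, nPerBlock, nVars - half)),
    cbind(matrix(0, nPerBlock, half), matrix(1, nPerBlock, nVars - half)))
}

.checkSpec <- function(scenario, q, sigmaPair, nPerBlock, nVars) {
  if (!scenario %in% .SCENARIOS)
    stop("scenario must be one of ", paste(.SCENARIOS, collapse = ", "))
  if (!is.numeric(q) || length(q) != 1L || q <= 0) stop("q must be a single positive number")
  if (scenario == "sd3") {
    if (length(sigmaPair) != 2L || any(sigmaPair <= 0))
      stop("sigmaPair must be two positive standard deviations")
    if (sigmaPair[1] == sigmaPair[2])
      stop("sd3 requires two *different* noise standard deviations")
  }
  if (nPerBlock < 2L || nVars < 4L) stop("degenerate simulation size")
}

# prototype rows (per datatype) and 4-or-2-class truth for each scenario,
# for an arbitrary ordered vector of class labels
.scenarioPrototypes <- function(scenario, classOf, nVars) {
  m <- length(classOf)
  half <- nVars %/% 2L
  onesAt <- function(rows, cols) {
    p <- matrix(0, m, nVars); p[rows, cols] <- 1; p
  }
  switch(scenario,
    sd1 = ,
    sd2 = ,
    sd3 = {
      p <- onesAt(which(classOf == 1L), seq_len(half)) +
           onesAt(which(classOf == 2L), (half + 1L):nVars)
      list(p, p)
    },
    sd4 = list(
      onesAt(which(classOf == 1L), seq_len(half)),
      onesAt(which(classOf == 2L), (half + 1L):nVars)),
    sd5 = list(
      onesAt(which(classOf %in% c(1L, 2L)), seq_len(half)) +
        onesAt(which(classOf %in% c(3L, 4L)), (half + 1L):nVars),
      onesAt(which(classOf %in% c(1L, 4L)), seq_len(half)) +
        onesAt(which(classOf %in% c(2L, 3L)), (half + 1L):nVars)))
}

# class label per patient in the simplistic design; sd5 splits the two
# blocks of 2b patients into 4 classes of sizes (0.6b, 0.4b, 0.4b, 0.6b)
.scenarioClasses <- function(scenario, nPerBlock) {
  if (scenario == "sd5") {
    a <- round(0.6 * nPerBlock)
    rep(1:4, times = c(a, nPerBlock - a, nPerBlock - a, a))
  } else rep(1:2, each = nPerBlock)
}

#' Generate one simulation scenario
#'
#' Builds the two observed datatype matrices of a scenario from planted
#' block prototypes, together with the ground-truth class labels. With
#' `realistic = TRUE` the design is augmented the way real cohorts look:
#' the second class is doubled in size, a block of unclassified patients
#' (pure noise, `NA` label) is appended, and each datatype gains 10 times
#' as many uninformative standard-normal feature columns as informative
#' ones.
#'
#' @param scenario one of `"sd1"` .. `"sd5"`; see the package vignette for
#'   what each isolates.
#' @param q scenario control parameter: the power/base of the two scale
#'   transforms for `sd1`, the noise scale (normal sd / uniform upper
#'   bound) for `sd2`, `sd4`, `sd5`. Ignored by `sd3`.
#' @param sigmaPair the two (different) normal noise sds of `sd3`.
#' @param realistic logical; apply the realistic augmentation.
#' @param seed integer seed; identical arguments give bit-identical output.
#' @param nPerBlock patients per planted block (default 50, i.e. 100
#'   patients in the simplistic design).
#' @param nVars number of informative variables per datatype (default 100).
#' @return A [SimulationOutput-class].
#' @details For `sd1` the standard-normal noise is added to the prototype
#'   *before* the elementwise power (`T1 = D0^q`) and exponential
#'   (`T2 = q^D0`) transforms — both observed datatypes are deterministic
#'   transforms of the same noisy hidden matrix, which is what makes their
#'   scales conflict while their rank structure partially survives. At
#'   `q = 1` the exponential datatype degenerates to a constant matrix and
#'   a warning is emitted.
#' @examples
#' sim <- simulateScenario("sd5", q = 1, seed = 42)
#' table(trueLabels(sim))
#' @export
simulateScenario <- function(scenario = .SCENARIOS, q = 1,
                             sigmaPair = c(0.5, 2), realistic = FALSE,
                             seed = 1, nPerBlock = 50L, nVars = 100L) {
  scenario <- match.arg(scenario)
  .checkSpec(scenario, q, sigmaPair, nPerBlock, nVars)
  if (scenario == "sd1" && q == 1)
    warning("q = 1 makes the exponential datatype constant (1^x); the scenario is degenerate")
  set.seed(as.integer(seed %% .Machine$integer.max))

  classOf <- .scenarioClasses(scenario, nPerBlock)
  mask <- rep(FALSE, length(classOf))
  if (realistic) {
    classOf <- c(classOf, rep(2L, sum(classOf == 2L)))   # second subtype doubled
    mask <- c(rep(FALSE, length(classOf)), rep(TRUE, nPerBlock))
    classOf <- c(classOf, rep(NA_integer_, nPerBlock))   # unclassified patients
  }
  m <- length(classOf)
  ids <- sprintf("P%03d", seq_len(m))
  protos <- .scenarioPrototypes(scenario, classOf, nVars)
  protos <- lapply(protos, function(p) { p[is.na(classOf), ] <- 0; p })

  observed <- switch(scenario,
    sd1 = {
      d0 <- protos[[1]] + matrix(stats::rnorm(m * nVars), m, nVars)
      list(d0^q, q^d0)
    },
    sd2 = list(
      protos[[1]] + matrix(stats::rnorm(m * nVars, sd = q), m, nVars),
      protos[[2]] + matrix(stats::runif(m * nVars, 0, q), m, nVars)),
    sd3 = list(
      protos[[1]] + matrix(stats::rnorm(m * nVars, sd = sigmaPair[1]), m, nVars),
      protos[[2]] + matrix(stats::rnorm(m * nVars, sd = sigmaPair[2]), m, nVars)),
    lapply(protos, function(p)                            # sd4, sd5
      p + matrix(stats::rnorm(m * nVars, sd = q), m, nVars)))

  if (realistic)
    observed <- lapply(observed, function(x)
      cbind(x, matrix(stats::rnorm(m * 10L * nVars), m, 10L * nVars)))

  datasets <- lapply(seq_along(observed), function(k) {
    v <- observed[[k]]
    dimnames(v) <- list(ids, paste0("f", seq_len(ncol(v))))
    OmicsMatrix(v, datatype = paste0("data", k))
  })
  new("SimulationOutput", datasets = datasets, trueLabels = classOf,
      unclassifiedMask = mask, scenario = scenario,
      params = list(q = q, sigmaPair = if (scenario == "sd3") sigmaPair else NULL,
                    realistic = realistic, seed = seed,
                    nPerBlock = nPerBlock, nVars = nVars))
}

#' Apply the realistic augmentation to a simplistic simulation
#'
#' Regenerates the scenario of `base` under the realistic design (doubled
#' second class, unclassified patients, 10x uninformative features) with
#' fresh noise draws; the original noise realizations are deliberately not
#' reused. Applying it to an already-realistic output is an error.
#'
#' @param base a [SimulationOutput-class] from [simulateScenario()] with
#'   `realistic = FALSE`.
#' @param seed seed for the regenerated draws; defaults to the base seed.
#' @return A [SimulationOutput-class] in realistic mode.
#' @export
realisticAugment <- function(base, seed = NULL) {
  stopifnot(is(base, "SimulationOutput"))
  p <- base@params
  if (isTRUE(p$realistic))
    stop("simulation is already in realistic mode; augmenting twice is not meaningful")
  if (is.null(seed)) seed <- p$seed
  simulateScenario(base@scenario, q = p$q,
                   sigmaPair = if (is.null(p$sigmaPair)) c(0.5, 2) else p$sigmaPair,
                   realistic = TRUE, seed = seed,
                   nPerBlock = p$nPerBlock, nVars = p$nVars)
}
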