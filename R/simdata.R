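#' Generate a synthetic molecular descriptor table with known structure
#'
#' Emulates the statistical shape of the bundled benchmark so every pipeline
#' stage can be exercised on data with known ground truth: a block of
#' `n_relevant` jointly Gaussian descriptors with pairwise (equicorrelated)
#' correlation `rho` drives the target through a smooth function;
#' `n_noise` further descriptors are independent standard normal noise.
#' The experimental BDE is the target function of the relevant block plus
#' Gaussian noise; the calculated BDE column (`dH_homo`) is the experimental
#' value minus a systematic offset and a Gaussian calculation error,
#' emulating the structure of uncorrected DFT deviations on the benchmark
#' (offset ~2.4, error sd ~5.3 kcal/mol by default).
#'
#' Descriptor columns take the first `1 + n_relevant + n_noise` canonical
#' names ([yno_descriptors()]): `dH_homo`, then the relevant block, then the
#' noise block, so the generated CSV is schema-compatible with
#' [read_descriptor_table()].  Generation is fully reproducible per `seed`
#' and leaves the caller's RNG state untouched.
#'
#' @param n Number of molecules.
#' @param n_relevant Relevant descriptors (equicorrelated block), >= 1.
#' @param n_noise Irrelevant noise descriptors;
#'   `1 + n_relevant + n_noise <= 12`.
#' @param rho Pairwise correlation within the relevant block, in \[0, 1).
#' @param target One of `"linear"`, `"quadratic"`, `"sinusoidal"`.
#' @param noise_sd Standard deviation of the experimental noise (kcal/mol).
#' @param calc_offset,calc_sd Systematic offset and error sd of the
#'   emulated calculated-BDE column.
#' @param test_fraction Fraction of molecules flagged `test`, in (0, 1).
#' @param seed Integer seed.
#' @return Descriptor table (data frame) with attribute `sim_truth`: a list
#'   recording the generating settings and the relevant/noise column names.
#' @examples
#' tab <- simulate_descriptor_table(n = 50, seed = 1)
#' sim_structure(tab)$relevant
#' @export
simulate_descriptor_table <- function(n = 92L, n_relevant = 3L, n_noise = 4L,
                                      rho = 0.6,
                                      target = c("linear", "quadratic",
                                                 "sinusoidal"),
                                      noise_sd = 0.5,
                                      calc_offset = 2.4, calc_sd = 5.3,
                                      test_fraction = 12 / 92,
                                      seed = 1L) {
  target <- match.arg(target)
  if (n_relevant < 1L) stop("need at least one relevant descriptor")
  if (1L + n_relevant + n_noise > 12L)
    stop("1 + n_relevant + n_noise must not exceed the 12 descriptor slots")
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  if (n < 4L) stop("need at least 4 molecules")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, globalenv())
  } else if (exists(".Random.seed", globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)

  # equicorrelated Gaussian block: Z = sqrt(rho) * common + sqrt(1-rho) * own
  common <- stats::rnorm(n)
  relevant <- sqrt(rho) * matrix(common, n, n_relevant) +
    sqrt(1 - rho) * matrix(stats::rnorm(n * n_relevant), n, n_relevant)
  f <- switch(target,
    linear = function(z) 25 + 3 * rowMeans(z) * sqrt(ncol(z)),
    quadratic = function(z) 25 + 2 * rowMeans(z) * sqrt(ncol(z)) +
      1.5 * rowMeans(z)^2 * ncol(z),
    sinusoidal = function(z) 25 + 5 * sin(rowMeans(z) * sqrt(ncol(z))))
  expt <- f(relevant) + stats::rnorm(n, sd = noise_sd)
  dh <- expt - (calc_offset + stats::rnorm(n, sd = calc_sd))
  noise <- if (n_noise > 0L) {
    matrix(stats::rnorm(n * n_noise), n, n_noise)
  } else {
    matrix(numeric(0), n, 0L)
  }

  slots <- yno_descriptors()
  rel_names <- slots[2L:(1L + n_relevant)]
  noise_names <- if (n_noise > 0L) {
    slots[(2L + n_relevant):(1L + n_relevant + n_noise)]
  } else {
    character(0)
  }
  n_test <- max(1L, round(n * test_fraction))
  split <- rep("train", n)
  split[sample.int(n, n_test)] <- "test"

  table <- data.frame(mol_id = seq_len(n), bond_class = "SIM",
                      split = split, expt_bde = expt, dH_homo = dh)
  for (j in seq_len(n_relevant)) table[[rel_names[j]]] <- relevant[, j]
  for (j in seq_len(n_noise)) table[[noise_names[j]]] <- noise[, j]
  attr(table, "sim_truth") <- list(n = n, n_relevant = n_relevant,
                                   n_noise = n_noise, rho = rho,
                                   target = target, noise_sd = noise_sd,
                                   calc_offset = calc_offset,
                                   calc_sd = calc_sd, seed = seed,
                                   relevant = rel_names, noise = noise_names)
  table
}

#' Ground-truth structure report for a simulated table
#'
#' Returns the generating settings of a table produced by
#' [simulate_descriptor_table()] together with relevance labels per
#' descriptor column and the realized correlation matrix of the relevant
#' block, for use in assertions about structure recovery.
#'
#' @param table Table generated by [simulate_descriptor_table()].
#' @return List with the generator settings plus `labels` (named character
#'   vector, `"relevant"`/`"noise"`/`"calculated"` per descriptor column)
#'   and `realized_correlation` (sample correlation matrix of the relevant
#'   columns).
#' @export
sim_structure <- function(table) {
  truth <- attr(table, "sim_truth")
  if (is.null(truth))
    stop("table was not produced by simulate_descriptor_table()")
  missing_cols <- setdiff(c(truth$relevant, truth$noise), names(table))
  if (length(missing_cols))
    stop("table does not match its sim_truth attribute: missing ",
         paste(missing_cols, collapse = ", "))
  desc <- descriptor_names(table)
  labels <- stats::setNames(rep("noise", length(desc)), desc)
  labels[truth$relevant] <- "relevant"
  labels["dH_homo"] <- "calculated"
  truth$labels <- labels
  truth$realized_correlation <-
    stats::cor(as.matrix(table[, truth$relevant, drop = FALSE]))
  truth
}
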