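#' Default full-factorial parameter grid
#'
#' The study grid for the generator's performance protocol: link density
#' \code{l_d} in \{0.01, 0.05, 0.1\}, landscape continuity \code{gamma} in
#' \{0, 0.5, 1, 1.5, 2\}, kernel width \code{sigma_d} in \{0.01, 0.1, 0.2,
#' 0.3\} (multiples of the reference diagonal D), focal scale factor
#' \code{fsf} in \{10, 100, 1000\} and focal fraction \code{f} in \{0,
#' 0.05, 0.1, 0.15, 0.2\} - 900 combinations in full crossing, run at n =
#' 500 on a 100 x 100 landscape with exponential kernel shape.
#'
#' @return named list of factor levels.
#' @export
default_sweep_grid <- function() {
  list(l_d = c(0.01, 0.05, 0.1),
       gamma = c(0, 0.5, 1, 1.5, 2),
       sigma_d = c(0.01, 0.1, 0.2, 0.3),
       fsf = c(10, 100, 1000),
       f = c(0, 0.05, 0.1, 0.15, 0.2))
}

# Deterministic per-run seed from (base_seed, combination, replicate),
# kept inside the 32-bit signed range.
derive_seed <- function(base_seed, comb, rep) {
  as.integer((as.double(base_seed) + 1000003 * comb + 7919 * rep) %%
               .Machine$integer.max + 1)
}

#' Run a full-factorial parameter sweep
#'
#' Generates every grid combination times \code{replicates} networks and
#' computes the structure measures of each. Per-run seeds are derived
#' deterministically from \code{base_seed} and the row's combination and
#' replicate indices, so any single row can be regenerated independently.
#' Combinations that fail to generate are recorded as failed rows
#' (measures \code{NA}) rather than aborting the sweep. An optional
#' checkpoint file makes long sweeps resumable.
#'
#' @param grid named list of factor levels (see [default_sweep_grid()]).
#' @param replicates networks per combination.
#' @param base_seed integer master seed.
#' @param n,l_size,kappa held constant across the sweep.
#' @param checkpoint optional path to a TSV checkpoint; completed
#'   combinations found there are not recomputed.
#' @param verbose print progress every 50 combinations.
#' @return \code{data.frame} of class \code{"specnet_sweep"}: one row per
#'   network with factor levels, replicate index, seed and measures
#'   (undefined assortativity stored as \code{NA}).
#' @export
specnet_sweep <- function(grid = default_sweep_grid(), replicates = 3,
                          base_seed = 1, n = 500, l_size = 100,
                          kappa = 10 / 3, checkpoint = NULL,
                          verbose = FALSE) {
  stopifnot(replicates >= 1)
  combos <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.delim(checkpoint)
    if (!nrow(done)) done <- NULL
  }
  rows <- vector("list", nrow(combos))
  for (ci in seq_len(nrow(combos))) {
    if (!is.null(done) && any(done$comb == ci)) {
      rows[[ci]] <- done[done$comb == ci, , drop = FALSE]
      next
    }
    cmb <- combos[ci, , drop = FALSE]
    reps <- lapply(seq_len(replicates), function(r) {
      sd_r <- derive_seed(base_seed, ci, r)
      meas <- tryCatch({
        net <- specnet(n = n, l_d = cmb$l_d, gamma = cmb$gamma,
                       sigma_d = cmb$sigma_d, fsf = cmb$fsf, f = cmb$f,
                       kappa = kappa, l_size = l_size, seed = sd_r)
        network_measures(net)
      }, error = function(e)
        data.frame(clustering = NA_real_, assortativity = NA_real_,
                   fragmentation = NA_real_, mean_degree = NA_real_,
                   link_density = NA_real_))
      cbind(comb = ci, cmb, replicate = r, seed = sd_r, meas,
            row.names = NULL)
    })
    rows[[ci]] <- do.call(rbind, reps)
    if (!is.null(checkpoint))
      utils::write.table(do.call(rbind, rows[seq_len(ci)]), checkpoint,
                         sep = "\t", row.names = FALSE, quote = FALSE)
    if (verbose && ci %% 50 == 0)
      message(sprintf("sweep: %d / %d combinations", ci, nrow(combos)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("specnet_sweep", "data.frame")
  out
}

#' Quantile table of sweep measures
#'
#' Summary statistics (min, 1%, 10%, median, 90%, 99%, max; linear
#' interpolation) of each structure measure over a subset of sweep rows.
#' Undefined assortativity rows are excluded from that measure's quantiles
#' and their count reported.
#'
#' @param result a \code{"specnet_sweep"} data frame.
#' @param subset optional logical vector or expression selecting rows
#'   (e.g. \code{result$gamma == 0}).
#' @param measures which measure columns to summarise.
#' @return \code{data.frame}: one row per measure with the quantile columns
#'   and \code{n_defined}.
#' @export
sweep_quantiles <- function(result,
                            subset = NULL,
                            measures = c("clustering", "assortativity",
                                         "fragmentation")) {
  df <- as.data.frame(result)
  if (!is.null(subset)) df <- df[subset, , drop = FALSE]
  if (!nrow(df)) stop("empty subset")
  probs <- c(0, 0.01, 0.10, 0.5, 0.90, 0.99, 1)
  out <- lapply(measures, function(m) {
    v <- df[[m]]
    v <- v[!is.na(v)]
    q <- stats::quantile(v, probs = probs, type = 7, names = FALSE)
    data.frame(measure = m, min = q[1], q01 = q[2], q10 = q[3],
               median = q[4], q90 = q[5], q99 = q[6], max = q[7],
               n_defined = length(v))
  })
  do.call(rbind, out)
}

#' Factorial ANOVA decomposition of a sweep response
#'
#' Fits a fixed-effects ANOVA with all five main effects (\code{l_d},
#' \code{gamma}, \code{sigma_d}, \code{fsf}, \code{f}, as factors) and all
#' two-way interactions to one structure measure over the sweep, and
#' expresses each term's mean square (MS = Sum Sq / Df) as a percentage of
#' the summed MS over all model terms (the residual is excluded from the
#' denominator). Interactions are reported individually and pooled into a
#' single \code{combinations} category. On the balanced full-factorial
#' design the type-I decomposition is order-invariant; a warning is issued
#' if the design is unbalanced.
#'
#' @param result a \code{"specnet_sweep"} data frame.
#' @param response one of \code{"clustering"}, \code{"assortativity"},
#'   \code{"fragmentation"}. Rows with an undefined value are dropped
#'   (count reported as an attribute).
#' @return named numeric vector of MS percentages for the five main
#'   effects, each pairwise interaction, and \code{combinations} (pooled
#'   interactions); attribute \code{n_dropped} carries the dropped-row
#'   count.
#' @export
sweep_anova <- function(result, response = "clustering") {
  df <- as.data.frame(result)
  if (!response %in% names(df)) stop("unknown response: ", response)
  keep <- !is.na(df[[response]])
  n_dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (stats::var(df[[response]]) == 0)
    stop("constant response: ANOVA decomposition undefined")
  factors <- c("l_d", "gamma", "sigma_d", "fsf", "f")
  for (fc in factors) df[[fc]] <- factor(df[[fc]])
  tab <- table(df[factors])
  if (length(unique(as.vector(tab))) > 1L)
    warning("design is unbalanced; sums of squares are order-dependent",
            call. = FALSE)
  form <- stats::as.formula(paste(response, "~ (l_d + gamma + sigma_d + fsf + f)^2"))
  an <- stats::anova(stats::lm(form, data = df))
  terms <- rownames(an) != "Residuals"
  ms <- an[terms, "Mean Sq"]
  names(ms) <- rownames(an)[terms]
  pct <- 100 * ms / sum(ms)
  inter <- grepl(":", names(pct))
  out <- c(pct, combinations = sum(pct[inter]))
  attr(out, "n_dropped") <- n_dropped
  out
}
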