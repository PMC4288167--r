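#' Precompute an occupancy model for a genome, PWM and accessibility
#'
#' Scans the genome on both strands, applies the relative-score filter that
#' selects the reported sites, attaches per-site accessibilities and sets up
#' the per-lambda cache of Boltzmann weights. The resulting object is the
#' reusable input of [predict_chip_profile()], [grid_search()] and
#' [fit_occupancy()].
#'
#' @param genome DNA string (single sequence).
#' @param pwm a `tf_pwm` object.
#' @param accessibility per-base accessibility track or `NULL` (naked DNA).
#' @param threshold relative-score filter fraction (default 0.7).
#' @param threshold_mode filter mode, see [filter_by_relative_score()].
#' @param ploidy genome copies per nucleus (default 2).
#' @param chrom sequence label.
#' @return object of class `occupancy_model`.
#' @export
occupancy_model <- function(genome, pwm, accessibility = NULL,
                            threshold = 0.7,
                            threshold_mode = c("offset_from_min",
                                               "absolute_range"),
                            ploidy = 2L, chrom = "chr1") {
  threshold_mode <- match.arg(threshold_mode)
  all_sites <- score_sequence(pwm, genome, chrom = chrom)
  filt <- filter_by_relative_score(all_sites, threshold, threshold_mode)
  if (nrow(filt) == 0L)
    stop("the relative-score filter retained no sites ",
         "(mode '", threshold_mode, "', fraction ", threshold, ")")
  L <- attr(all_sites, "seq_length")
  m <- attr(all_sites, "motif_length")
  aw <- .window_accessibility(accessibility, L, m)
  structure(list(
    chrom = chrom, L = L, m = m, ploidy = as.integer(ploidy),
    pwm = pwm,
    accessibility = accessibility,
    all_scores = all_sites$score,
    all_acc = aw[all_sites$start],
    n_slots = attr(all_sites, "n_slots"),
    score_range = attr(all_sites, "score_range"),
    sites = as.data.frame(filt),
    site_acc = aw[filt$start],
    site_centers = filt$start + floor((m - 1) / 2),
    threshold = threshold, threshold_mode = threshold_mode,
    cache = new.env(parent = emptyenv())),
    class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("Occupancy model on %s (%d bp, ploidy %d)\n", x$chrom, x$L,
              x$ploidy))
  cat(sprintf("  motif '%s' (%d bp), %d scored windows\n", x$pwm$name, x$m,
              length(x$all_scores)))
  cat(sprintf("  %d reported sites above the %.0f%% relative-score ",
              nrow(x$sites), 100 * x$threshold))
  cat(sprintf("threshold (%s)\n", x$threshold_mode))
  cat(sprintf("  accessibility: %s\n",
              if (is.null(x$accessibility)) "naked DNA (a = 1)"
              else sprintf("%.1f%% accessible mass",
                           100 * mean(as.numeric(x$accessibility)))))
  invisible(x)
}

# per-lambda cached quantities: genomic average weight and the filtered-site
# weights; identical results whether cached or recomputed
.lambda_terms <- function(model, lambda) {
  key <- sprintf("%.12g", lambda)
  hit <- model$cache[[key]]
  if (!is.null(hit)) return(hit)
  w_all <- boltzmann_weight(model$all_scores, lambda)
  tot <- sum(model$all_acc * w_all)
  if (tot <= 0)
    stop("all sites are inaccessible: the occupancy model is undefined")
  val <- list(avg = tot / model$n_slots,
              site_weight = boltzmann_weight(model$sites$score, lambda))
  model$cache[[key]] <- val
  val
}

#' Site occupancies under a precomputed model
#'
#' @param model an `occupancy_model`.
#' @param N,lambda model parameters.
#' @return numeric vector of per-site binding probabilities (order of
#'   `model$sites`).
#' @export
site_probabilities <- function(model, N, lambda) {
  stopifnot(inherits(model, "occupancy_model"))
  if (length(N) != 1L || !is.finite(N) || N <= 0)
    stop("'N' must be a single positive number")
  lt <- .lambda_terms(model, lambda)
  num <- N * model$site_acc * lt$site_weight
  num / (num + model$n_slots * model$ploidy * lt$avg)
}

#' Predict a ChIP-seq-like profile from the occupancy model
#'
#' Occupancy probabilities for the reported sites, extended with the fragment
#' kernel and smoothed -- the deterministic part of the generative pipeline.
#'
#' @param model an `occupancy_model`.
#' @param N,lambda model parameters.
#' @param kernel optional precomputed `fragment_kernel`.
#' @param fragment_mean,fragment_sd,smooth_window profile parameters.
#' @return numeric per-base profile of length `model$L`.
#' @export
predict_chip_profile <- function(model, N, lambda, kernel = NULL,
                                 fragment_mean = 200, fragment_sd = 200,
                                 smooth_window = 250) {
  if (is.null(kernel)) kernel <- fragment_kernel(fragment_mean, fragment_sd)
  p <- site_probabilities(model, N, lambda)
  prof <- extend_occupancy_to_coverage(model$site_centers, p, model$L,
                                       kernel = kernel)
  smooth_profile(prof, smooth_window)
}

# mean of the zero-censored observation max(0, p + eps), eps ~ N(0, sigma);
# identity when sigma = 0
.censored_mean <- function(p, sigma) {
  if (sigma <= 0) return(p)
  p * stats::pnorm(p / sigma) + sigma * stats::dnorm(p / sigma)
}

# noise scale estimated from bases where the model predicts zero signal:
# inaccessible chromatin at least `margin` bp away from any accessible base,
# so that fragment-kernel leakage from nearby sites cannot reach them. There
# the observation is max(0, eps), whose mean is sigma * dnorm(0).
.estimate_noise_sigma <- function(observed, accessibility, margin = 2000L) {
  if (is.null(accessibility)) return(0)
  a <- as.numeric(accessibility)
  L <- length(a)
  cs <- c(0, cumsum(a > 0))
  i <- seq_len(L)
  lo <- pmax(0L, i - margin - 1L)
  hi <- pmin(L, i + margin)
  far <- (cs[hi + 1L] - cs[lo + 1L]) == 0
  if (sum(far) < 1000L) return(0)
  mean(observed[far]) / stats::dnorm(0)
}

#' Default parameter grids for the grid search
#'
#' Log-spaced molecule numbers spanning 1 to 1e6 and specificity factors
#' 0.25 to 5 in steps of 0.25.
#' @return numeric vector.
#' @export
default_N_grid <- function() {
  c(1, 10, 100, 500, 1000, 2000, 5000, 1e4, 2e4, 5e4, 1e5, 1e6)
}

#' @rdname default_N_grid
#' @export
default_lambda_grid <- function() seq(0.25, 5, by = 0.25)

#' Grid search over molecule number and specificity
#'
#' For every (N, lambda) pair the model profile is predicted, optionally
#' passed through the zero-censoring observation mean (when a noise scale is
#' known or estimable), and compared with the observed profile by Pearson
#' correlation and by mean squared error over `bin`-bp windows. The genomic
#' Boltzmann average is computed once per lambda (it does not depend on N).
#'
#' @param observed per-base observed profile, length `model$L`.
#' @param model an `occupancy_model` (or build one by passing `genome`, `pwm`
#'   and `accessibility` to [fit_occupancy()]).
#' @param N_grid,lambda_grid parameter grids.
#' @param bin MSE bin width, bp.
#' @param normalization profile normalization inside the MSE, see
#'   [normalized_mse()].
#' @param metric_domain `"accessible"` restricts both metrics to bins
#'   containing at least one accessible base (the analysed loci); `"all"`
#'   uses the whole region; or an integer vector of bin indices.
#' @param noise_model `"censored"` compares the observation mean of the
#'   zero-truncated noise model (noise scale estimated from inaccessible
#'   bases); `"none"` compares the clean model profile.
#' @param fragment_mean,fragment_sd,smooth_window profile parameters.
#' @return object of class `occupancy_grid`: list with `N_grid`,
#'   `lambda_grid`, matrices `rho` and `mse` (rows = N, columns = lambda),
#'   `noise_sigma` and the call parameters.
#' @export
grid_search <- function(observed, model, N_grid = default_N_grid(),
                        lambda_grid = default_lambda_grid(), bin = 1000,
                        normalization = c("none", "mean", "max"),
                        metric_domain = "accessible",
                        noise_model = c("censored", "none"),
                        fragment_mean = 200, fragment_sd = 200,
                        smooth_window = 250) {
  normalization <- match.arg(normalization)
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(model, "occupancy_model"))
  if (!length(N_grid) || !length(lambda_grid))
    stop("parameter grids must be non-empty")
  if (length(observed) != model$L)
    stop("observed profile length (", length(observed),
         ") does not match the model region (", model$L, " bp)")
  obs_bin_all <- bin_profile(observed, bin)
  if (stats::sd(obs_bin_all) == 0)
    stop("observed profile is degenerate (zero variance)")
  dom <- .resolve_domain(metric_domain, model, bin, length(obs_bin_all))
  sigma <- if (noise_model == "censored")
    .estimate_noise_sigma(observed, model$accessibility) else 0
  obs_dom <- obs_bin_all[dom]
  obs_norm <- tryCatch(.normalize_profile(obs_dom, normalization),
                       error = function(e) NULL)
  if (is.null(obs_norm))
    stop("observed profile is all zero over the metric domain")
  kernel <- fragment_kernel(fragment_mean, fragment_sd)
  nr <- length(N_grid); nc <- length(lambda_grid)
  rho <- mse <- matrix(NA_real_, nr, nc,
                       dimnames = list(format(N_grid, trim = TRUE,
                                              scientific = FALSE),
                                       format(lambda_grid, trim = TRUE)))
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      prof <- predict_chip_profile(model, N_grid[i], lambda_grid[j],
                                   kernel = kernel,
                                   smooth_window = smooth_window)
      pb <- bin_profile(.censored_mean(prof, sigma), bin)[dom]
      rho[i, j] <- tryCatch(pearson_correlation(pb, obs_dom),
                            error = function(e) NA_real_)
      mse[i, j] <- tryCatch(
        mean((.normalize_profile(pb, normalization) - obs_norm)^2),
        error = function(e) NA_real_)
    }
  }
  structure(list(N_grid = N_grid, lambda_grid = lambda_grid,
                 rho = rho, mse = mse, noise_sigma = sigma,
                 bin = bin, normalization = normalization,
                 metric_domain = dom, noise_model = noise_model),
            class = "occupancy_grid")
}

.resolve_domain <- function(metric_domain, model, bin, n_bins) {
  if (is.numeric(metric_domain)) {
    dom <- as.integer(metric_domain)
    if (any(dom < 1L) || any(dom > n_bins))
      stop("metric_domain bin indices out of range")
    return(dom)
  }
  if (identical(metric_domain, "all") || is.null(model$accessibility))
    return(seq_len(n_bins))
  if (identical(metric_domain, "accessible")) {
    acc_bin <- bin_profile(as.numeric(model$accessibility), bin)
    dom <- which(acc_bin > 0)
    if (!length(dom)) stop("no accessible bins in the region")
    return(dom)
  }
  stop("'metric_domain' must be \"accessible\", \"all\" or bin indices")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("Occupancy fit grid: %d N values x %d lambda values\n",
              length(x$N_grid), length(x$lambda_grid)))
  cat(sprintf("  rho in [%.3f, %.3f]; MSE in [%.3g, %.3g]\n",
              min(x$rho, na.rm = TRUE), max(x$rho, na.rm = TRUE),
              min(x$mse, na.rm = TRUE), max(x$mse, na.rm = TRUE)))
  invisible(x)
}

#' Select the optimal parameter set from a fit grid
#'
#' Marks the cells whose MSE lies in the lowest `band_fraction` of the MSE
#' range and whose correlation lies in the highest `band_fraction` of the
#' correlation range, and returns the minimum-MSE cell inside the
#' intersection of the two bands. If the bands do not intersect, the global
#' minimum-MSE cell is returned and flagged. Ties break towards smaller N,
#' then smaller lambda.
#'
#' @param grid an `occupancy_grid`.
#' @param band_fraction band width as a fraction of each metric's range
#'   (default 0.12).
#' @return object of class `occupancy_optimum`: list with `N_opt`,
#'   `lambda_opt`, `rho_at_opt`, `mse_at_opt`, `rho_max`, `mse_min`,
#'   `intersection` (data frame of cells in both bands), and flags
#'   `intersection_empty` and `degenerate`.
#' @export
select_optimum <- function(grid, band_fraction = 0.12) {
  stopifnot(inherits(grid, "occupancy_grid"))
  rho <- grid$rho; mse <- grid$mse
  if (all(is.na(rho)) || all(is.na(mse)))
    stop("grid contains no finite metric values")
  rho_rng <- range(rho, na.rm = TRUE)
  mse_rng <- range(mse, na.rm = TRUE)
  degenerate <- (rho_rng[1] == rho_rng[2]) && (mse_rng[1] == mse_rng[2])
  in_rho <- !is.na(rho) & rho >= rho_rng[2] - band_fraction * diff(rho_rng)
  in_mse <- !is.na(mse) & mse <= mse_rng[1] + band_fraction * diff(mse_rng)
  inter <- in_rho & in_mse
  intersection_empty <- !any(inter)
  cand <- if (intersection_empty) {
    which(!is.na(mse) & mse == mse_rng[1], arr.ind = TRUE)
  } else {
    which(inter, arr.ind = TRUE)
  }
  cand <- matrix(cand, ncol = 2)
  ord <- order(mse[cand], cand[, 1], cand[, 2])
  best <- cand[ord[1], ]
  inter_cells <- which(inter, arr.ind = TRUE)
  structure(list(
    N_opt = grid$N_grid[best[1]],
    lambda_opt = grid$lambda_grid[best[2]],
    rho_at_opt = rho[best[1], best[2]],
    mse_at_opt = mse[best[1], best[2]],
    rho_max = rho_rng[2], mse_min = mse_rng[1],
    band_fraction = band_fraction,
    intersection = data.frame(
      N = grid$N_grid[inter_cells[, 1]],
      lambda = grid$lambda_grid[inter_cells[, 2]],
      rho = rho[inter_cells], mse = mse[inter_cells]),
    in_rho_band = in_rho, in_mse_band = in_mse,
    intersection_empty = intersection_empty,
    degenerate = degenerate),
    class = "occupancy_optimum")
}

#' @export
print.occupancy_optimum <- function(x, ...) {
  cat(sprintf("Optimal parameters: N = %s, lambda = %.2f\n",
              format(x$N_opt, big.mark = ","), x$lambda_opt))
  cat(sprintf("  rho = %.3f (max %.3f); MSE = %.4g (min %.4g)\n",
              x$rho_at_opt, x$rho_max, x$mse_at_opt, x$mse_min))
  if (x$degenerate)
    cat("  [flat grid: all cells equal, first cell reported]\n")
  else if (x$intersection_empty)
    cat("  [rho and MSE bands do not intersect: global MSE minimum reported]\n")
  else
    cat(sprintf("  %d grid cells in the %.0f%% band intersection\n",
                nrow(x$intersection), 100 * x$band_fraction))
  invisible(x)
}

#' Fit the occupancy model to an observed binding profile
#'
#' The main entry point: estimates the number of DNA-bound molecules `N` and
#' the specificity factor `lambda` of a transcription factor from an observed
#' ChIP-seq-like profile, given the genome sequence, the factor's PWM and
#' (optionally) a DNA accessibility track. A grid search evaluates the
#' Pearson correlation and binned mean squared error between the model
#' profile and the observation for every parameter pair, and the optimum is
#' the minimum-MSE cell within the intersection of the top-correlation and
#' bottom-MSE bands ([select_optimum()]): the correlation surface constrains
#' lambda while the MSE surface constrains N.
#'
#' @param observed numeric per-base observed profile.
#' @param genome DNA string; ignored when `model` is given.
#' @param pwm a `tf_pwm`; ignored when `model` is given.
#' @param accessibility per-base accessibility or `NULL`.
#' @param model optional precomputed [occupancy_model()].
#' @param N_grid,lambda_grid parameter grids.
#' @param threshold,threshold_mode relative-score filter settings.
#' @param ploidy genome copies per nucleus.
#' @param band_fraction selection band width.
#' @param ... further arguments to [grid_search()] (`bin`, `normalization`,
#'   `metric_domain`, `noise_model`, `fragment_mean`, `fragment_sd`,
#'   `smooth_window`).
#' @return object of class `occupancy_fit` with components `model`, `grid`,
#'   `optimum`, `observed` and the profile parameters; supports `print()`,
#'   `summary()`, `coef()`, `predict()`, `fitted()`, `residuals()`,
#'   `simulate()` and `plot()`.
#' @examples
#' \donttest{
#' fx <- make_fixture(synthetic_spec(genome_length = 50000, seed = 7))
#' fit <- fit_occupancy(fx$observed, fx$genome, fx$pwm, fx$accessibility,
#'                      N_grid = c(1000, 5000, 20000),
#'                      lambda_grid = c(1, 1.5, 2))
#' coef(fit)
#' }
#' @export
fit_occupancy <- function(observed, genome = NULL, pwm = NULL,
                          accessibility = NULL, model = NULL,
                          N_grid = default_N_grid(),
                          lambda_grid = default_lambda_grid(),
                          threshold = 0.7,
                          threshold_mode = "offset_from_min",
                          ploidy = 2L, band_fraction = 0.12, ...) {
  if (is.null(model)) {
    if (is.null(genome) || is.null(pwm))
      stop("provide either a precomputed 'model' or 'genome' and 'pwm'")
    model <- occupancy_model(genome, pwm, accessibility,
                             threshold = threshold,
                             threshold_mode = threshold_mode,
                             ploidy = ploidy)
  }
  grid <- grid_search(observed, model, N_grid = N_grid,
                      lambda_grid = lambda_grid, ...)
  opt <- select_optimum(grid, band_fraction)
  dots <- list(...)
  prof_par <- list(
    fragment_mean = dots$fragment_mean %||% 200,
    fragment_sd = dots$fragment_sd %||% 200,
    smooth_window = dots$smooth_window %||% 250)
  structure(list(model = model, grid = grid, optimum = opt,
                 observed = observed, profile_params = prof_par,
                 call = match.call()),
            class = "occupancy_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.occupancy_fit <- function(x, ...) {
  cat("Transcription factor occupancy fit\n")
  print(x$model)
  print(x$optimum)
  invisible(x)
}

#' @export
coef.occupancy_fit <- function(object, ...) {
  c(N = object$optimum$N_opt, lambda = object$optimum$lambda_opt)
}

#' @export
summary.occupancy_fit <- function(object, ...) {
  opt <- object$optimum
  top <- opt$intersection
  if (nrow(top)) top <- top[order(top$mse), , drop = FALSE]
  structure(list(fit = object,
                 coef = coef(object),
                 n_sites = nrow(object$model$sites),
                 noise_sigma = object$grid$noise_sigma,
                 intersection = utils::head(top, 10L)),
            class = "summary.occupancy_fit")
}

#' @export
print.summary.occupancy_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  estimated noise sd: %.4g\n", x$noise_sigma))
  if (nrow(x$intersection)) {
    cat("  best band-intersection cells:\n")
    print(x$intersection, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Predict profiles or site occupancies from a fitted model
#'
#' @param object an `occupancy_fit`.
#' @param N,lambda parameters; default to the fitted optimum. Supplying a
#'   different `N` predicts the profile for, e.g., nuclei with a different
#'   local TF abundance.
#' @param type `"profile"` (per-base signal) or `"sites"` (per-site
#'   probabilities).
#' @param ... unused.
#' @return numeric profile, or the site table with probabilities.
#' @export
predict.occupancy_fit <- function(object, N = NULL, lambda = NULL,
                                  type = c("profile", "sites"), ...) {
  type <- match.arg(type)
  N <- N %||% object$optimum$N_opt
  lambda <- lambda %||% object$optimum$lambda_opt
  pp <- object$profile_params
  if (type == "sites") {
    out <- object$model$sites
    out$accessibility <- object$model$site_acc
    out$probability <- site_probabilities(object$model, N, lambda)
    return(out)
  }
  predict_chip_profile(object$model, N, lambda,
                       fragment_mean = pp$fragment_mean,
                       fragment_sd = pp$fragment_sd,
                       smooth_window = pp$smooth_window)
}

#' @export
fitted.occupancy_fit <- function(object, ...) {
  predict(object, type = "profile")
}

#' @export
residuals.occupancy_fit <- function(object, ...) {
  object$observed - fitted(object)
}

#' Simulate replicate observed profiles from a fitted model
#'
#' Forward-simulates `nsim` noisy profiles at the fitted (or supplied)
#' parameters, using the noise scale estimated during fitting unless
#' overridden.
#'
#' @param object an `occupancy_fit`.
#' @param nsim number of replicates.
#' @param seed optional integer seed (applied locally).
#' @param N,lambda,noise_sd overrides; defaults: fitted optimum and the
#'   estimated noise sd.
#' @param ... unused.
#' @return matrix with one column per replicate.
#' @export
simulate.occupancy_fit <- function(object, nsim = 1, seed = NULL, N = NULL,
                                   lambda = NULL, noise_sd = NULL, ...) {
  base <- predict(object, N = N, lambda = lambda)
  noise_sd <- noise_sd %||% object$grid$noise_sigma
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  out <- vapply(seq_len(nsim),
                function(i) add_truncated_noise(base, noise_sd),
                numeric(length(base)))
  colnames(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot an occupancy fit
#'
#' `type = "surfaces"` draws the correlation and MSE heatmaps over the
#' parameter grid with the 12%-band cells and the selected optimum marked;
#' `type = "profile"` overlays the observed and fitted profiles.
#'
#' @param x an `occupancy_fit`.
#' @param type `"surfaces"` or `"profile"`.
#' @param ... further graphical arguments (ignored).
#' @return `x`, invisibly.
#' @export
plot.occupancy_fit <- function(x, type = c("surfaces", "profile"), ...) {
  type <- match.arg(type)
  g <- x$grid; opt <- x$optimum
  if (type == "surfaces") {
    old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
    on.exit(graphics::par(old))
    for (metric in c("rho", "mse")) {
      z <- g[[metric]]
      band <- if (metric == "rho") opt$in_rho_band else opt$in_mse_band
      graphics::image(x = seq_along(g$N_grid), y = seq_along(g$lambda_grid),
                      z = z, xlab = "N (grid index)", ylab = "lambda",
                      axes = FALSE,
                      col = grDevices::hcl.colors(64, if (metric == "rho")
                        "YlOrRd" else "Blues", rev = metric == "rho"),
                      main = if (metric == "rho") "Pearson correlation"
                             else "mean squared error")
      graphics::axis(1, at = seq_along(g$N_grid),
                     labels = format(g$N_grid, scientific = TRUE, digits = 1),
                     las = 2, cex.axis = 0.6)
      graphics::axis(2, at = seq_along(g$lambda_grid),
                     labels = g$lambda_grid, cex.axis = 0.6)
      wb <- which(band, arr.ind = TRUE)
      graphics::points(wb[, 1], wb[, 2], pch = 0, cex = 0.8)
      graphics::points(match(opt$N_opt, g$N_grid),
                       match(opt$lambda_opt, g$lambda_grid),
                       pch = 19, col = "green3")
      graphics::box()
    }
  } else {
    fit_prof <- fitted(x)
    graphics::plot(x$observed, type = "h", col = "grey70",
                   xlab = sprintf("position on %s (bp)", x$model$chrom),
                   ylab = "signal", main = "observed (grey) vs fitted (red)")
    graphics::lines(fit_prof, col = "red", lwd = 1.5)
  }
  invisible(x)
}
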