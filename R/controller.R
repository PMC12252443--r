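ANTECEDENTS <- c("sugar_gL", "pH", "co2", "biomass_gL", "temp_C")
CONSEQUENT <- "alcohol_gL"

#' Train the fuzzy alcohol soft sensor
#'
#' Calibrates a Mamdani fuzzy inference system that infers alcohol
#' concentration from sugar, pH, CO2, biomass and temperature.  Each of the
#' six attributes gets a data-driven three-class Gaussian partition built
#' from the pooled training values ([build_partition()]), and the rule base
#' is induced by Wang-Mendel-style grid learning: every training sample votes
#' for the rule formed by its argmax class per antecedent and consequent with
#' a weight equal to the product of the winning memberships; for each
#' distinct antecedent combination the consequent with the largest
#' accumulated weight is kept, and the rule weight is the maximum
#' single-sample product observed for that winning pair.
#'
#' @param curves List of fermentation curves (data.frames) carrying all six
#'   attributes, including the alcohol label.
#' @param smoothing_sigma Gaussian smoothing bandwidth (samples) applied by
#'   [infer_series()] (default 2).
#' @param k,kd Partition hyperparameters passed to [build_partition()].
#' @param grid_points Number of points discretising the consequent universe
#'   for centroid defuzzification.
#' @param implication Consequent implication operator: `"scale"` (default;
#'   product/Larsen implication, which keeps the centroid invariant to a
#'   common rescaling of the firing strengths) or `"clip"` (classical
#'   Mamdani truncation).
#' @return A list of class `alcohol_controller` with `partitions` (six
#'   `gaussian_partition`s), `rules` (data.frame of antecedent classes,
#'   consequent class and weight), and inference settings.
#' @export
train_controller <- function(curves, smoothing_sigma = 2, k = 3, kd = 1,
                             grid_points = 201,
                             implication = c("scale", "clip")) {
  implication <- match.arg(implication)
  if (is.data.frame(curves)) curves <- list(curves)
  if (length(curves) < 1) stop("need at least one training curve")
  needed <- c(ANTECEDENTS, CONSEQUENT)
  for (cv in curves) {
    missing <- setdiff(needed, names(cv))
    if (length(missing)) {
      stop("curve is missing attribute(s): ", paste(missing, collapse = ", "))
    }
  }
  pooled <- do.call(rbind, lapply(curves, function(cv) {
    as.data.frame(cv)[, needed]
  }))

  partitions <- lapply(needed, function(a) {
    build_partition(compute_stats(pooled[[a]]), name = a, k = k, kd = kd)
  })
  names(partitions) <- needed

  # class memberships of every pooled sample, per attribute
  memb <- lapply(needed, function(a) partition_memberships(partitions[[a]],
                                                           pooled[[a]]))
  names(memb) <- needed
  win_class <- vapply(memb, function(m) max.col(m, ties.method = "first"),
                      integer(nrow(pooled)))
  win_memb <- vapply(needed, function(a) {
    memb[[a]][cbind(seq_len(nrow(pooled)), win_class[, a])]
  }, numeric(nrow(pooled)))
  sample_weight <- apply(win_memb, 1, prod)

  combo <- apply(win_class[, ANTECEDENTS, drop = FALSE], 1, paste,
                 collapse = "-")
  key <- paste(combo, win_class[, CONSEQUENT], sep = "|")
  acc <- tapply(sample_weight, key, sum)
  mx <- tapply(sample_weight, key, max)
  parts <- strsplit(names(acc), "|", fixed = TRUE)
  cand <- data.frame(combo = vapply(parts, `[`, "", 1),
                     consequent = as.integer(vapply(parts, `[`, "", 2)),
                     acc = as.numeric(acc), wmax = as.numeric(mx))
  # per antecedent combination keep the consequent with the largest
  # accumulated weight
  cand <- cand[order(cand$combo, -cand$acc), ]
  rules_raw <- cand[!duplicated(cand$combo), ]
  ante <- do.call(rbind, strsplit(rules_raw$combo, "-", fixed = TRUE))
  ante <- matrix(as.integer(ante[, seq_along(ANTECEDENTS)]),
                 nrow = nrow(rules_raw))
  colnames(ante) <- ANTECEDENTS
  rules <- data.frame(ante, consequent = rules_raw$consequent,
                      weight = pmin(rules_raw$wmax, 1))
  rownames(rules) <- NULL

  structure(list(partitions = partitions, rules = rules,
                 smoothing_sigma = smoothing_sigma,
                 grid_points = grid_points,
                 implication = implication,
                 activation_floor = 1e-6,
                 antecedents = ANTECEDENTS, consequent = CONSEQUENT),
            class = "alcohol_controller")
}

# Defuzzification grid over the consequent universe.
consequent_grid <- function(controller) {
  u <- controller$partitions[[controller$consequent]]$universe
  seq(u[1], u[2], length.out = controller$grid_points)
}

# Firing strengths of all rules for a matrix of samples (rows) of the five
# antecedents: min over antecedent memberships, times the rule weight.
rule_strengths <- function(controller, samples) {
  n <- nrow(samples)
  rules <- controller$rules
  strengths <- matrix(1, n, nrow(rules))
  for (a in controller$antecedents) {
    part <- controller$partitions[[a]]
    x <- pmin(pmax(samples[[a]], part$universe[1]), part$universe[2])
    m <- partition_memberships(part, x)
    strengths <- pmin(strengths, m[, rules[[a]], drop = FALSE])
  }
  sweep(strengths, 2, rules$weight, `*`)
}

#' Infer alcohol concentration for one or more samples
#'
#' Mamdani inference: rule firing strength is the minimum antecedent
#' membership times the rule weight; consequent memberships are clipped at
#' the aggregated (max) strength of their class and defuzzified by centroid
#' over the discretised consequent universe.  Samples outside a partition
#' universe are clipped to it.  If no rule fires above the activation floor
#' the midpoint of the consequent universe is returned with a warning.
#'
#' @param controller An `alcohol_controller` from [train_controller()].
#' @param sample A named numeric vector, list, or data.frame with the five
#'   antecedent attributes (data.frames are processed row-wise).
#' @return Inferred alcohol concentration(s) in g/L, within the consequent
#'   universe.
#' @export
infer_alcohol <- function(controller, sample) {
  stopifnot(inherits(controller, "alcohol_controller"))
  if (nrow(controller$rules) == 0) stop("controller has an empty rule base")
  if (!is.data.frame(sample)) sample <- as.data.frame(as.list(sample))
  missing <- setdiff(controller$antecedents, names(sample))
  if (length(missing)) {
    stop("sample is missing attribute(s): ", paste(missing, collapse = ", "))
  }

  s <- rule_strengths(controller, sample)
  # aggregate per consequent class (max), then centroid of the clipped
  # consequent membership functions
  classes <- controller$rules$consequent
  agg <- vapply(1:3, function(cl) {
    cols <- which(classes == cl)
    if (!length(cols)) return(rep(0, nrow(sample)))
    apply(s[, cols, drop = FALSE], 1, max)
  }, numeric(nrow(sample)))
  agg <- matrix(agg, nrow = nrow(sample), ncol = 3)

  z <- consequent_grid(controller)
  cmemb <- partition_memberships(controller$partitions[[controller$consequent]], z)

  clip <- identical(controller$implication %||% "scale", "clip")
  out <- vapply(seq_len(nrow(sample)), function(i) {
    mu <- if (clip) {
      # Mamdani clipping: consequent MFs truncated at the firing strength
      pmin(matrix(agg[i, ], length(z), 3, byrow = TRUE), cmemb)
    } else {
      # scaling (product) implication: robust for weak activations because
      # the centroid is invariant to a common rescaling of the strengths
      matrix(agg[i, ], length(z), 3, byrow = TRUE) * cmemb
    }
    mu <- apply(mu, 1, max)
    if (max(agg[i, ]) < controller$activation_floor) {
      warning("no rule fired above the activation floor; returning the ",
              "consequent-universe midpoint")
      return(mean(range(z)))
    }
    sum(z * mu) / sum(mu)
  }, numeric(1))
  out
}

#' Infer a smoothed alcohol series for a whole curve
#'
#' Pointwise [infer_alcohol()] over the curve followed by Gaussian smoothing
#' with the controller's `smoothing_sigma`.
#'
#' @param controller An `alcohol_controller`.
#' @param curve A fermentation curve (data.frame) with the five antecedent
#'   attributes.
#' @return Smoothed alcohol series (g/L), same length as the curve.
#' @export
infer_series <- function(controller, curve) {
  raw <- infer_alcohol(controller, as.data.frame(curve))
  gaussian_smooth(raw, controller$smoothing_sigma)
}

#' Resample a fermentation curve to a finer time step
#'
#' Linear interpolation of every attribute onto a uniform grid with the
#' requested step, used to pad hourly measurements to 5-minute resolution.
#'
#' @param curve A fermentation curve (data.frame with `time_h`).
#' @param step_min Target sampling interval in minutes.
#' @return A resampled curve (data.frame, `fermentation_curve`).
#' @export
resample_curve <- function(curve, step_min = 5) {
  t_new <- seq(min(curve$time_h), max(curve$time_h), by = step_min / 60)
  out <- data.frame(time_h = t_new)
  for (a in setdiff(names(curve), "time_h")) {
    out[[a]] <- approx(curve$time_h, curve[[a]], xout = t_new)$y
  }
  attributes(out) <- c(attributes(out),
                       attributes(curve)[c("seed", "params", "draws",
                                           "noisy", "alcohol_source")])
  class(out) <- c("fermentation_curve", "data.frame")
  out
}

#' @export
print.alcohol_controller <- function(x, ...) {
  cat(sprintf("<alcohol_controller: %d rules, 5 antecedents -> %s, smoothing sigma %.3g>\n",
              nrow(x$rules), x$consequent, x$smoothing_sigma))
  invisible(x)
}
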