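#' Simulated isotropic Gaussian blobs
#'
#' Generates `n_per_class` cases per class in two dimensions, class `c` drawn
#' from an isotropic Gaussian around a fixed center. Centers are equally
#' spaced on a circle of radius 10, so the amount of class overlap is
#' governed solely by `cluster_sd` (the study uses SDs 2, 4 and 6 for
#' increasing overlap).
#'
#' @param n_per_class Cases per class (>= 1).
#' @param n_classes 2 or 3 classes.
#' @param cluster_sd Isotropic standard deviation of each cluster (> 0).
#' @param seed Integer seed; identical parameters and seed reproduce the
#'   table bit for bit.
#' @return A [case_table()] with `2 * n_per_class` or `3 * n_per_class`
#'   cases, classes in generation order (all class 0, then class 1, ...).
#' @examples
#' tab <- make_blobs(100, 2, cluster_sd = 2, seed = 1)
#' table(tab$labels)
#' @export
make_blobs <- function(n_per_class, n_classes, cluster_sd, seed) {
  check_generator_args(n_per_class, n_classes)
  if (!is.numeric(cluster_sd) || length(cluster_sd) != 1 || cluster_sd <= 0)
    stop("cluster_sd must be a single positive number")
  angles <- 2 * pi * (seq_len(n_classes) - 1) / n_classes
  centers <- cbind(10 * cos(angles), 10 * sin(angles))
  withr::with_seed(as.integer(seed), {
    feats <- do.call(rbind, lapply(seq_len(n_classes), function(c) {
      cbind(stats::rnorm(n_per_class, centers[c, 1], cluster_sd),
            stats::rnorm(n_per_class, centers[c, 2], cluster_sd))
    }))
  })
  case_table(feats, rep(seq_len(n_classes) - 1L, each = n_per_class),
             n_classes = n_classes,
             feature_names = c("x1", "x2"),
             provenance = sprintf(
               "make_blobs: n_per_class=%d n_classes=%d cluster_sd=%g seed=%d",
               n_per_class, n_classes, cluster_sd, as.integer(seed)))
}

# Noiseless crescent arcs: class 0 is the upper unit semicircle; class 1 is
# the standard interleaving lower semicircle shifted right by 1 and down by
# 0.5; class 2 repeats the class-0 arc translated by the same-orientation
# inter-arc offset (+2 in x), preserving the interleaving pattern.
moon_arc <- function(n, class_id) {
  t <- seq(0, pi, length.out = n)
  shift <- (class_id %/% 2) * 2
  if (class_id %% 2 == 0) {
    cbind(cos(t) + shift, sin(t))
  } else {
    cbind(1 - cos(t) + shift, 0.5 - sin(t))
  }
}

#' Simulated interleaving crescent moons
#'
#' Points are placed evenly along semicircular arcs, one arc per class with
#' alternating orientation and offset so consecutive crescents interleave,
#' then jittered with isotropic Gaussian noise. The study uses noise SDs
#' 0.1, 0.2 and 0.4 for increasing overlap.
#'
#' @inheritParams make_blobs
#' @param noise_sd SD of the isotropic Gaussian noise (>= 0; 0 gives the
#'   noiseless arcs).
#' @return A [case_table()].
#' @export
make_moons <- function(n_per_class, n_classes, noise_sd, seed) {
  check_generator_args(n_per_class, n_classes)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  feats <- do.call(rbind, lapply(seq_len(n_classes) - 1L, function(c)
    moon_arc(n_per_class, c)))
  withr::with_seed(as.integer(seed), {
    feats <- feats + matrix(stats::rnorm(length(feats), 0, noise_sd),
                            nrow(feats), 2)
  })
  case_table(feats, rep(seq_len(n_classes) - 1L, each = n_per_class),
             n_classes = n_classes,
             feature_names = c("x1", "x2"),
             provenance = sprintf(
               "make_moons: n_per_class=%d n_classes=%d noise_sd=%g seed=%d",
               n_per_class, n_classes, noise_sd, as.integer(seed)))
}

#' Simulated concentric circles
#'
#' Class 0 lies on the unit circle; each subsequent class lies on a circle
#' shrunk by successive powers of `scale_factor` (radii 1, f, f^2), with
#' isotropic Gaussian noise. The study uses scale factors 0.3, 0.5 and 0.7.
#'
#' @inheritParams make_blobs
#' @param scale_factor Ratio between successive radii, in (0, 1).
#' @param noise_sd SD of the added Gaussian noise (default 0.05).
#' @return A [case_table()].
#' @export
make_circles <- function(n_per_class, n_classes, scale_factor,
                         noise_sd = 0.05, seed) {
  check_generator_args(n_per_class, n_classes)
  if (!is.numeric(scale_factor) || length(scale_factor) != 1 ||
      scale_factor <= 0 || scale_factor >= 1)
    stop("scale_factor must lie strictly between 0 and 1")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  feats <- do.call(rbind, lapply(seq_len(n_classes) - 1L, function(c) {
    t <- seq(0, 2 * pi, length.out = n_per_class + 1)[seq_len(n_per_class)]
    r <- scale_factor^c
    cbind(r * cos(t), r * sin(t))
  }))
  withr::with_seed(as.integer(seed), {
    if (noise_sd > 0)
      feats <- feats + matrix(stats::rnorm(length(feats), 0, noise_sd),
                              nrow(feats), 2)
  })
  case_table(feats, rep(seq_len(n_classes) - 1L, each = n_per_class),
             n_classes = n_classes,
             feature_names = c("x1", "x2"),
             provenance = sprintf(
               "make_circles: n_per_class=%d n_classes=%d scale_factor=%g noise_sd=%g seed=%d",
               n_per_class, n_classes, scale_factor, noise_sd,
               as.integer(seed)))
}

check_generator_args <- function(n_per_class, n_classes) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1 || n_per_class < 1)
    stop("n_per_class must be a positive integer")
  if (!n_classes %in% c(2L, 3L))
    stop("n_classes must be 2 or 3")
  invisible(TRUE)
}
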