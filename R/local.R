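# Local structure of a point cloud: intrinsic dimension by local PCA and
# boundary/singularity detection by local (annulus) persistent homology.

#' Local dimension by PCA of k-nearest neighbourhoods
#'
#' For every point, a PCA of its k nearest Euclidean neighbours gives the
#' explained-variance curve; the local dimension is the drop-off (elbow)
#' of that curve, located with a maximum-curvature criterion: the
#' component at which the spectrum falls by the largest factor, i.e. the
#' sharpest corner of the log-scree curve.  Interior points of a clean
#' d-manifold sample give d.
#'
#' @param cloud a [point_cloud()] (neighbourhoods use ambient Euclidean
#'   distance regardless of the cloud's metric).
#' @param k neighbourhood size (70 for attractor-condition population
#'   clouds, 20 for the no-attractor condition).
#' @param max_components cap on the number of PCA components examined.
#' @return integer vector of per-point local dimensions, with attribute
#'   `fraction` (table of dimension frequencies as proportions).
#' @export
local_dimension <- function(cloud, k = 70, max_components = 20) {
  pts <- cloud$points
  n <- nrow(pts)
  if (k >= n) stop("k must be below the number of points")
  if (k < 3) stop("k must be at least 3")
  DE <- if (cloud$metric == "euclidean") cloud$dist else as.matrix(dist(pts))
  dims <- integer(n)
  for (i in seq_len(n)) {
    nb <- order(DE[i, ], seq_len(n))[2:(k + 1)]
    X <- scale(pts[nb, , drop = FALSE], center = TRUE, scale = FALSE)
    sv <- svd(X, nu = 0, nv = 0)$d
    ev <- sv^2
    ev <- ev[ev > 0]
    m <- min(length(ev), max_components)
    if (m < 2) { dims[i] <- 1L; next }
    dims[i] <- elbow_dimension(ev[1:m] / sum(ev))
  }
  structure(dims, fraction = table(dims) / n)
}

# drop-off of a decreasing explained-variance-ratio curve: the first
# sufficiently sharp corner of the log-scree curve, i.e. the first
# multiplicative gap reaching at least half of the largest gap.  Taking
# the first qualifying drop (rather than the global maximum) keeps weak
# curvature shelves after the true drop from inflating the dimension;
# tiny trailing eigenvalues are floored so that ratios between noise
# components cannot dominate.
elbow_dimension <- function(ev, floor_frac = 1e-4, first_frac = 0.5) {
  ev <- pmax(ev, floor_frac * ev[1])
  gaps <- log(ev[-length(ev)] / ev[-1])
  which(gaps >= first_frac * max(gaps))[1]
}

#' Local first Betti number in an annulus neighbourhood
#'
#' For every point, the points ranked `k1` to `k2` by Euclidean distance
#' form an annular neighbourhood whose degree-1 persistent homology is
#' computed; local beta1 is the number of H1 generators above a cutoff
#' shared by all points (the automated histogram cutoff applied to the
#' pooled annulus diagrams, mirroring the global procedure).  On a sample
#' of a closed surface, interior points give beta1 = 1, boundary points 0
#' and cone-like singularities more than 1.
#'
#' @param cloud a [point_cloud()].
#' @param k1,k2 annulus ranks (50/100 for attractor conditions, 10/30 for
#'   the no-attractor condition).
#' @param field coefficient prime for the local diagrams.
#' @param cutoff `"pooled"` (one cutoff from the pooled annulus diagrams,
#'   the default) or `"per_point"` (each point thresholded against its own
#'   diagram).  The pooled rule is calibrated by the typical interior
#'   point; annuli with atypically sparse cycles (e.g. around a cone
#'   singularity, where the points split over several rings) can fall
#'   below a pooled threshold and may need the per-point rule.
#' @return integer vector of per-point local beta1 (NA when the annulus has
#'   fewer than 10 points), with attributes `cutoff` and `fraction`.
#' @export
local_beta1 <- function(cloud, k1 = 50, k2 = 100, field = 2,
                        cutoff = c("pooled", "per_point")) {
  cutoff <- match.arg(cutoff)
  pts <- cloud$points
  n <- nrow(pts)
  if (!(k1 < k2 && k2 <= n - 1)) stop("need k1 < k2 <= n_points - 1")
  DE <- if (cloud$metric == "euclidean") cloud$dist else as.matrix(dist(pts))
  lts <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- order(DE[i, ], seq_len(n))[(k1 + 1):(k2 + 1)]
    if (length(nb) < 10) { lts[[i]] <- NULL; next }
    sub <- DE[nb, nb]
    res <- cpp_rips_persistence(sub, 1L, as.integer(field), NA_real_)
    pd <- res$pairs[[2]]
    lt <- pd[, 2] - pd[, 1]
    lts[[i]] <- lt[is.finite(lt) & lt > 0]
  }
  if (cutoff == "pooled") {
    co <- lifetime_cutoff(unlist(lts))
    b1 <- vapply(seq_len(n), function(i) {
      if (is.null(lts[[i]])) return(NA_integer_)
      sum(lts[[i]] > co)
    }, integer(1))
  } else {
    co <- NA_real_
    b1 <- vapply(seq_len(n), function(i) {
      if (is.null(lts[[i]])) return(NA_integer_)
      sum(lts[[i]] > lifetime_cutoff(lts[[i]]))
    }, integer(1))
  }
  structure(b1, cutoff = as.numeric(co),
            fraction = table(b1, useNA = "no") / sum(!is.na(b1)))
}
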