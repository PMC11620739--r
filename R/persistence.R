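#' Vietoris-Rips persistent homology
#'
#' Computes persistence diagrams of a finite metric space in degrees 0 to
#' `max_degree` with coefficients in the prime field Z/`field`.  Degree 0
#' is computed by a union-find pass over the sorted edges; higher degrees
#' by persistent-cohomology matrix reduction with the clearing and
#' apparent-pair optimisations (compiled code).  By default the filtration
#' runs to the enclosing radius of the space, at which scale the Rips
#' complex becomes a cone, so every class of degree >= 1 dies within the
#' filtration and diagrams are complete.  The final stretch of the
#' filtration holds the bulk of the simplices, and occasional point
#' clouds produce pathologically heavy reduction chains there; if the
#' computation runs out of memory it is automatically retried with the
#' ceiling lowered to 0.85 and then 0.75 of the enclosing radius (classes
#' still alive at a lowered ceiling are closed there, so generators are
#' never lost — at most their deaths are capped).
#'
#' The single essential degree-0 generator (the surviving connected
#' component) is kept and assigned a finite display lifetime of 1.2 times
#' the largest finite lifetime in the diagram, so that it sits above the
#' noise but on a comparable scale.
#'
#' @param x a [point_cloud()], or a symmetric distance matrix.
#' @param max_degree highest homology degree (0, 1 or 2; default 2).
#' @param field coefficient field prime (2 or 3).
#' @param threshold filtration ceiling; `NULL` for the enclosing radius
#'   (with the automatic memory fallback described above).
#' @return object of class `rips_persistence`: data.frame `pairs` with
#'   columns `degree`, `birth`, `death`, `lifetime`, `essential`; plus
#'   `field`, `threshold`, `n_points`.  Zero-persistence pairs are omitted.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 41)[-41]
#' ps <- rips_persistence(cbind(cos(th), sin(th)), max_degree = 1)
#' summary(ps)
#' @export
rips_persistence <- function(x, max_degree = 2, field = 2,
                             threshold = NULL) {
  D <- if (inherits(x, "point_cloud")) x$dist
       else if (is.matrix(x) && nrow(x) == ncol(x)) x
       else as.matrix(dist(x))
  if (!field %in% c(2, 3)) stop("field must be the prime 2 or 3")
  base <- if (is.null(threshold)) cpp_enclosing_radius(D)
          else as.numeric(threshold)
  scales <- if (is.null(threshold)) c(1, 0.85, 0.75) else 1
  res <- NULL
  for (sc in scales) {
    res <- tryCatch(
      cpp_rips_persistence(D, as.integer(max_degree), as.integer(field),
                           base * sc),
      error = function(e) {
        if (grepl("alloc", conditionMessage(e), ignore.case = TRUE)) {
          gc()
          NULL  # retry with a lower filtration ceiling
        } else stop(e)
      })
    if (!is.null(res)) {
      if (sc < 1)
        message(sprintf(
          "rips_persistence: filtration ceiling lowered to %.2f of the enclosing radius (memory)", sc))
      break
    }
  }
  if (is.null(res))
    stop("persistence computation exceeded available memory at every ",
         "filtration ceiling")
  pairs <- do.call(rbind, lapply(0:max_degree, function(d) {
    pd <- res$pairs[[d + 1]]
    if (!nrow(pd)) return(NULL)
    data.frame(degree = d, birth = pd[, 1], death = pd[, 2])
  }))
  if (is.null(pairs))
    pairs <- data.frame(degree = integer(0), birth = numeric(0),
                        death = numeric(0))
  # a class still alive at the ceiling is closed at the ceiling
  inf_rows <- !is.finite(pairs$death)
  if (any(inf_rows)) pairs$death[inf_rows] <- res$threshold
  pairs$lifetime <- pairs$death - pairs$birth
  pairs <- pairs[pairs$lifetime > 0, , drop = FALSE]
  pairs$essential <- logical(nrow(pairs))
  # the essential H0 bar(s), with a finite display lifetime
  disp <- if (nrow(pairs)) 1.2 * max(pairs$lifetime)
          else max(res$threshold, 1)
  ess <- data.frame(degree = 0L, birth = 0, death = disp, lifetime = disp,
                    essential = TRUE)
  pairs <- rbind(pairs, ess[rep(1, res$essential_h0), ])
  pairs <- pairs[order(pairs$degree, -pairs$lifetime), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, field = field, threshold = res$threshold,
                 max_degree = max_degree, n_points = nrow(D)),
            class = "rips_persistence")
}

#' @export
print.rips_persistence <- function(x, ...) {
  cat(sprintf("rips_persistence: %d points, Z%d, threshold %.4g\n",
              x$n_points, x$field, x$threshold))
  for (d in sort(unique(x$pairs$degree))) {
    lt <- sort(x$pairs$lifetime[x$pairs$degree == d], decreasing = TRUE)
    cat(sprintf("  H%d: %d generators, top lifetimes %s\n", d, length(lt),
                paste(signif(head(lt, 3), 3), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.rips_persistence <- function(object, ...) print(object, ...)

#' @export
plot.rips_persistence <- function(x, ...) {
  p <- x$pairs
  cols <- c("grey40", "dodgerblue3", "firebrick3")
  graphics::plot(p$birth, p$lifetime, col = cols[p$degree + 1],
                 pch = ifelse(p$essential, 17, 19),
                 xlab = "birth", ylab = "lifetime", ...)
  graphics::legend("topright", legend = paste0("H", 0:max(p$degree)),
                   col = cols[1:(max(p$degree) + 1)], pch = 19, bty = "n")
  invisible(x)
}

#' Automated lifetime cutoff from a pooled diagram population
#'
#' Builds a 100-bin histogram of the pooled lifetimes between 0 and their
#' maximum, smooths it with a Gaussian kernel of 3-bin standard deviation,
#' finds the local minima of the smoothed curve and returns the lifetime at
#' the minimum showing the greatest fall from the preceding local maximum.
#' Generators with lifetimes above the cutoff are counted as signal.
#'
#' @param lifetimes numeric vector of pooled lifetimes, or a list of
#'   `rips_persistence` objects together with `degree`.
#' @param degree homology degree to pool when diagrams are supplied.
#' @param n_bins,smooth_sd histogram bins and Gaussian s.d. (in bins).
#' @return cutoff lifetime, with attribute `flagged` when no interior
#'   minimum exists (then the maximum lifetime is returned, i.e. everything
#'   is treated as noise).
#' @export
lifetime_cutoff <- function(lifetimes, degree = NULL, n_bins = 100,
                            smooth_sd = 3) {
  if (is.list(lifetimes)) {
    stopifnot(!is.null(degree))
    # essential bars participate through their display lifetimes: the
    # display value is chosen above the noise scale precisely so that the
    # histogram separates them
    lifetimes <- unlist(lapply(lifetimes, function(ps)
      ps$pairs$lifetime[ps$pairs$degree == degree]))
  }
  lifetimes <- lifetimes[is.finite(lifetimes) & lifetimes > 0]
  if (!length(lifetimes))
    return(structure(0, flagged = TRUE))
  mx <- max(lifetimes)
  if (mx <= 0 || length(unique(lifetimes)) == 1)
    return(structure(mx, flagged = TRUE))
  br <- seq(0, mx, length.out = n_bins + 1)
  cnt <- tabulate(pmin(findInterval(lifetimes, br, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
  ker <- stats::dnorm(-(3 * smooth_sd):(3 * smooth_sd), sd = smooth_sd)
  ker <- ker / sum(ker)
  pad <- (length(ker) - 1) / 2
  smooth <- stats::convolve(c(rep(0, pad), cnt, rep(0, pad)), rev(ker),
                            type = "filter")
  n <- length(smooth)
  # plateau-tolerant extrema: the first bin of a flat valley (e.g. the
  # empty stretch between the noise bump and isolated long-lived bars)
  # counts as a minimum
  is_min <- is_max <- logical(n)
  for (i in 2:(n - 1)) {
    is_min[i] <- smooth[i] <= smooth[i - 1] && smooth[i] <= smooth[i + 1] &&
      (smooth[i] < smooth[i - 1] || smooth[i] < smooth[i + 1])
    is_max[i] <- smooth[i] >= smooth[i - 1] && smooth[i] > smooth[i + 1]
  }
  is_max[1] <- smooth[1] > smooth[2]
  mins <- which(is_min)
  if (!length(mins)) return(structure(mx, flagged = TRUE))
  falls <- vapply(mins, function(i) {
    # fall from the local maximum immediately preceding this minimum;
    # only deep valleys qualify (below half their preceding maximum),
    # otherwise the shallow wiggles of a sparse histogram masquerade as
    # modes
    before <- which(is_max[1:i])
    prev_max <- if (length(before)) smooth[max(before)] else smooth[1]
    if (smooth[i] > 0.5 * prev_max) return(-Inf)
    prev_max - smooth[i]
  }, numeric(1))
  if (!any(is.finite(falls))) return(structure(mx, flagged = TRUE))
  best <- mins[which.max(falls)]
  centers <- (br[-1] + br[-length(br)]) / 2
  structure(centers[best], flagged = FALSE)
}

#' Betti numbers from a diagram and lifetime cutoffs
#'
#' Counts, per degree, the generators whose lifetime exceeds the
#' corresponding cutoff.  The essential degree-0 bar participates through
#' its display lifetime.
#'
#' @param ps a `rips_persistence` object.
#' @param cutoffs numeric vector of per-degree cutoffs (recycled; named
#'   entries `"0"`, `"1"`, `"2"` are honoured).
#' @return integer vector `c(b0, b1, b2, ...)` up to the highest degree in
#'   the diagram.
#' @export
count_betti <- function(ps, cutoffs) {
  degs <- 0:(if (is.null(ps$max_degree)) max(ps$pairs$degree, 0)
             else ps$max_degree)
  if (!is.null(names(cutoffs))) {
    co <- rep(Inf, length(degs))
    co[match(names(cutoffs), as.character(degs))] <- cutoffs
  } else co <- rep_len(cutoffs, length(degs))
  b <- vapply(seq_along(degs), function(i) {
    sum(ps$pairs$degree == degs[i] & ps$pairs$lifetime > co[i])
  }, integer(1))
  stats::setNames(b, paste0("b", degs))
}
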