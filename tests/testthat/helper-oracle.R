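# Brute-force persistent homology: full boundary-matrix reduction over
# Z/p.  Independent of the package's reduction engine (dense matrices,
# left-to-right column algorithm, homology rather than cohomology); used
# as the ground-truth oracle on small complexes.
# Total simplexwise order: (diameter, dimension, colex index) ascending,
# matching the engine's filtration refinement.
brute_persistence <- function(D, max_dim = 2, p = 2, threshold = NULL) {
  n <- nrow(D)
  if (is.null(threshold)) threshold <- min(apply(D, 1, max))
  simp <- list()
  for (d in 0:(max_dim + 1)) {
    if (d + 1 > n) break
    combs <- utils::combn(n, d + 1)
    for (ci in seq_len(ncol(combs))) {
      v <- combs[, ci]
      diam <- if (d == 0) 0 else max(D[v, v][upper.tri(diag(d + 1))])
      if (diam <= threshold) {
        idx <- sum(choose(v - 1, seq_len(d + 1)))
        simp[[length(simp) + 1]] <- list(v = v, dim = d, diam = diam,
                                         idx = idx)
      }
    }
  }
  o <- order(vapply(simp, `[[`, 0, "diam"), vapply(simp, `[[`, 0L, "dim"),
             vapply(simp, `[[`, 0, "idx"))
  simp <- simp[o]
  m <- length(simp)
  pos <- stats::setNames(seq_len(m), vapply(simp, function(s)
    paste(sort(s$v), collapse = "-"), ""))
  cols <- vector("list", m)
  for (j in seq_len(m)) {
    s <- simp[[j]]
    col <- integer(m)
    if (s$dim > 0) {
      for (i in seq_along(s$v)) {
        r <- pos[[paste(sort(s$v[-i]), collapse = "-")]]
        col[r] <- (col[r] + (-1)^(i - 1)) %% p
      }
    }
    cols[[j]] <- col
  }
  low <- function(col) {
    nz <- which(col != 0)
    if (length(nz)) max(nz) else 0L
  }
  inv_mod <- function(c, p) {
    c <- c %% p
    for (x in 1:(p - 1)) if ((c * x) %% p == 1) return(x)
    stop("no inverse")
  }
  pivot_of <- integer(m)
  pairs <- list()
  for (j in seq_len(m)) {
    col <- cols[[j]]
    repeat {
      l <- low(col)
      if (l == 0L || pivot_of[l] == 0L) break
      jj <- pivot_of[l]
      lam <- (-col[l] * inv_mod(cols[[jj]][l], p)) %% p
      col <- (col + lam * cols[[jj]]) %% p
    }
    cols[[j]] <- col
    l <- low(col)
    if (l > 0L) {
      pivot_of[l] <- j
      pairs[[length(pairs) + 1]] <- list(dim = simp[[l]]$dim,
                                         birth = simp[[l]]$diam,
                                         death = simp[[j]]$diam)
    }
  }
  is_paired <- logical(m)
  for (pr in seq_len(m)) {
    if (pivot_of[pr] != 0) {
      is_paired[pr] <- TRUE
      is_paired[pivot_of[pr]] <- TRUE
    }
  }
  dims <- vapply(simp, `[[`, 0L, "dim")
  out <- list()
  for (d in 0:max_dim) {
    fin <- Filter(function(pr) pr$dim == d && pr$death > pr$birth, pairs)
    out[[d + 1]] <- list(
      finite = if (length(fin))
        cbind(birth = vapply(fin, `[[`, 0, "birth"),
              death = vapply(fin, `[[`, 0, "death"))
      else matrix(0, 0, 2, dimnames = list(NULL, c("birth", "death"))),
      n_essential = sum(!is_paired & dims == d))
  }
  out
}

# finite positive-lifetime pairs of a rips_persistence object, sorted
finite_pairs <- function(ps, degree) {
  p <- ps$pairs[ps$pairs$degree == degree & !ps$pairs$essential, ]
  p <- p[order(p$birth, p$death), c("birth", "death")]
  m <- as.matrix(p)
  storage.mode(m) <- "double"
  m
}

oracle_pairs <- function(orc, degree) {
  m <- orc[[degree + 1]]$finite
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  storage.mode(m) <- "double"
  m
}
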