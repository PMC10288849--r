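#' Morphometric measures of a union of balls
#'
#' The morphometric approach expresses the hydration entropy of a solute as
#' a linear combination of four geometric measures of its excluded volume
#' (the union of atom spheres dilated by the solvent probe radius):
#' the volume V (A^3), the boundary area A (A^2), the integrated mean
#' curvature C (A, convention: a sphere of radius R gives 4*pi*R), and the
#' integrated Gaussian curvature X (dimensionless, any topological sphere
#' gives 4*pi).  These are the additively extended intrinsic volumes of the
#' convex ring (Hadwiger's characterization), so sharp reentrant edges where
#' two spheres cross contribute to C with the (negative) angle between the
#' outward normals, and X is 2*pi times the Euler characteristic of the
#' boundary surface.
#'
#' `measures_exact()` computes all four measures analytically from the
#' arrangement of sphere-sphere intersection circles (boundary arcs, triple
#' points, per-sphere Gauss-Bonnet assembly); the result is exact to
#' round-off for any union in generic position.  `measures_steiner_mc()` is
#' the stochastic backend for very large unions.
#'
#' @name morphometry
NULL

morph_names <- c("V", "A", "C", "X")

#' Closed-form measures of a single sphere
#' @param R sphere radius in Angstrom.
#' @return Named numeric vector (V, A, C, X).
#' @export
sphere_measures <- function(R) {
  stopifnot(is.finite(R), R > 0)
  c(V = 4 * pi * R^3 / 3, A = 4 * pi * R^2, C = 4 * pi * R, X = 4 * pi)
}

#' Closed-form volume of the intersection lens of two spheres
#'
#' @param r1,r2 sphere radii.
#' @param d center separation; must satisfy |r1-r2| < d < r1+r2.
#' @return Lens volume in A^3.
#' @export
lens_volume <- function(r1, r2, d) {
  stopifnot(d > abs(r1 - r2), d < r1 + r2)
  pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
}

## Exact arrangement kernel ---------------------------------------------

## Interval union on a circle, arcs = uncovered pieces.  `iv` is a matrix
## with columns (start in [0,2pi), width in (0,2pi), owner).  Returns a list
## with uncovered arcs (start, end, owner_start, owner_end) or full=TRUE /
## empty=TRUE flags.  Owners identify which covering cap terminates the
## covered region at each uncovered endpoint.
.circle_uncovered <- function(iv, tol = 1e-12) {
  if (nrow(iv) == 0L) return(list(full = TRUE, arcs = NULL))
  two_pi <- 2 * pi
  ## split intervals wrapping past 2*pi at 0, so nothing covers "just
  ## before" position 0 unless an event says so
  a <- iv[, 1L] %% two_pi; w <- iv[, 2L]
  b <- a + w
  wrap <- b > two_pi
  starts <- c(a, rep(0, sum(wrap)))
  ends <- c(pmin(b, two_pi), b[wrap] - two_pi)
  ev_pos <- c(starts, ends)
  ev_typ <- c(rep(1L, length(starts)), rep(-1L, length(ends)))
  o <- order(ev_pos, -ev_typ)   # at ties, openings first: no spurious gaps
  ev_pos <- ev_pos[o]; ev_typ <- ev_typ[o]
  covering <- 0L
  pos <- 0
  segs <- NULL
  for (i in seq_along(ev_pos)) {
    p <- ev_pos[i]
    if (ev_typ[i] == 1L) {
      if (covering == 0L && p > pos + tol) segs <- rbind(segs, c(pos, p))
      covering <- covering + 1L
    } else {
      covering <- covering - 1L
      if (covering == 0L) pos <- p
    }
  }
  if (covering != 0L) stop("internal error: unbalanced circle coverage sweep")
  if (pos < two_pi - tol) segs <- rbind(segs, c(pos, two_pi))
  if (is.null(segs)) return(list(empty = TRUE, arcs = NULL))
  ## join the wrap-around pair: a segment ending at 2*pi continues into one
  ## starting at 0
  first0 <- which(segs[, 1L] < tol)
  last2 <- which(segs[, 2L] > two_pi - tol)
  if (length(first0) == 1L && length(last2) == 1L && first0 != last2) {
    segs[last2, 2L] <- segs[first0, 2L] + two_pi
    segs <- segs[-first0, , drop = FALSE]
  }
  list(arcs = segs)
}

#' Exact morphometric measures of a union of balls
#'
#' Analytic evaluation of (V, A, C, X) for the union of the spheres in
#' `spheres` via the boundary-arc arrangement.  Spheres swallowed by a
#' larger sphere and exact duplicates are eliminated first; near-tangent
#' configurations (within `tol`) are rejected as degenerate rather than
#' silently resolved.
#'
#' @param spheres a [sphere_set].
#' @param tol degeneracy tolerance in Angstrom (default 1e-8).
#' @param max_spheres refuse larger inputs (the stochastic backend is the
#'   intended tool there); default 4000.
#' @return Named numeric vector (V, A, C, X).
#' @examples
#' measures_exact(sphere_set(matrix(0, 1, 3), 2.8))  # 4*pi*R^3/3, ...
#' @export
measures_exact <- function(spheres, tol = 1e-8, max_spheres = 4000L) {
  stopifnot(inherits(spheres, "sphere_set"))
  ctr <- spheres$centers
  rad <- spheres$radii
  n <- nrow(ctr)
  if (n > max_spheres)
    stop(sprintf(paste0("%d spheres exceeds the exact-backend limit (%d); ",
                        "use measures_steiner_mc()"), n, max_spheres))
  ## drop exact duplicates
  key <- paste(signif(ctr[, 1L], 12), signif(ctr[, 2L], 12),
               signif(ctr[, 3L], 12), signif(rad, 12))
  keep <- !duplicated(key)
  ctr <- ctr[keep, , drop = FALSE]; rad <- rad[keep]
  n <- nrow(ctr)
  if (n == 1L) return(sphere_measures(rad))
  dm <- as.matrix(stats::dist(ctr))
  ## tangency degeneracy checks
  sumr <- outer(rad, rad, "+"); difr <- abs(outer(rad, rad, "-"))
  off <- upper.tri(dm)
  bad_ext <- off & abs(dm - sumr) < tol
  bad_int <- off & dm > tol & abs(dm - difr) < tol
  if (any(bad_ext | bad_int)) {
    ij <- which(bad_ext | bad_int, arr.ind = TRUE)[1L, ]
    stop(sprintf("degenerate (near-tangent) sphere pair %d-%d; perturb or raise tol",
                 ij[1L], ij[2L]))
  }
  ## swallowed spheres contribute nothing to the union
  swallowed <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (any(dm[i, ] + rad[i] <= rad - tol)) swallowed[i] <- TRUE
  }
  if (any(swallowed)) {
    ctr <- ctr[!swallowed, , drop = FALSE]; rad <- rad[!swallowed]
    dm <- dm[!swallowed, !swallowed, drop = FALSE]
    n <- nrow(ctr)
  }
  if (n == 1L) return(sphere_measures(rad))

  V <- 0; A <- 0; C_edge <- 0; chi_sum <- 0
  n_arcs_open <- 0L; n_vertices <- 0L
  Asm <- 0  # smooth mean-curvature part

  for (i in seq_len(n)) {
    Ri <- rad[i]; ci <- ctr[i, ]
    J <- which(dm[i, ] < Ri + rad & dm[i, ] > 0)
    J <- setdiff(J, i)
    if (length(J) == 0L) {
      sm <- sphere_measures(Ri)
      V <- V + sm["V"]; A <- A + sm["A"]; Asm <- Asm + sm["A"] / Ri
      chi_sum <- chi_sum + 2
      next
    }
    d <- dm[i, J]
    rj <- rad[J]
    axes <- sweep(ctr[J, , drop = FALSE], 2L, ci, "-") / d
    costh <- (d^2 + Ri^2 - rj^2) / (2 * d * Ri)
    costh <- pmin(pmax(costh, -1), 1)
    sinth <- sqrt(pmax(0, 1 - costh^2))
    theta <- acos(costh)
    ## per-cap circle frames
    nn <- length(J)
    circ_o <- sweep(axes * (Ri * costh), 2L, ci, "+")  # circle centers
    circ_r <- Ri * sinth
    ## orthonormal u,v per axis
    umat <- matrix(0, nn, 3L); vmat <- matrix(0, nn, 3L)
    for (q in seq_len(nn)) {
      a <- axes[q, ]
      ref <- if (abs(a[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      u <- ref - sum(ref * a) * a; u <- u / sqrt(sum(u^2))
      v <- c(a[2L] * u[3L] - a[3L] * u[2L],
             a[3L] * u[1L] - a[1L] * u[3L],
             a[1L] * u[2L] - a[2L] * u[1L])
      umat[q, ] <- u; vmat[q, ] <- v
    }
    arcs_i <- list()     # each: list(j, o, a, rho, theta, phi ends, pts)
    vert_pts <- NULL     # 3D vertex coords on this sphere
    vert_arc_end <- NULL # arc index ending at vertex
    vert_arc_start <- NULL
    full_circles <- 0L
    Svec <- c(0, 0, 0)
    gb_arc <- 0  # sum of cos(theta)*dphi over boundary arcs
    for (q in seq_len(nn)) {
      jj <- J[q]
      o <- circ_o[q, ]; rho <- circ_r[q]; a <- axes[q, ]
      u <- umat[q, ]; v <- vmat[q, ]
      others <- setdiff(seq_len(nn), q)
      iv <- NULL
      dead <- FALSE
      for (p in others) {
        kk <- J[p]
        w <- o - ctr[kk, ]
        qq <- (rad[kk]^2 - sum(w * w) - rho^2) / (2 * rho)
        al <- sum(w * u); be <- sum(w * v)
        m <- sqrt(al^2 + be^2)
        if (m > 0 && abs(abs(qq) - m) < tol * 1e-1)
          stop(sprintf("degenerate tangency among spheres %d, %d, %d", i, jj, kk))
        if (qq >= m) { dead <- TRUE; break }      # circle inside ball kk
        if (qq <= -m) next                        # ball kk misses circle
        ## covered where al*cos(phi) + be*sin(phi) < qq,
        ## i.e. m*cos(phi - base) < qq
        base <- atan2(be, al)
        Del <- acos(pmin(pmax(qq / m, -1), 1))
        st <- base + Del          # covered interval (base+Del, base+2pi-Del)
        wd <- 2 * pi - 2 * Del
        st <- st %% (2 * pi)
        iv <- rbind(iv, c(st, wd, p))
      }
      if (dead) next
      res <- .circle_uncovered(if (is.null(iv)) matrix(0, 0, 3) else iv)
      if (!is.null(res$full) && res$full) {
        ## entire circle uncovered: closed boundary curve
        full_circles <- full_circles + 1L
        gb_arc <- gb_arc + costh[q] * 2 * pi
        Svec <- Svec - pi * rho^2 * a
        C_edge <- C_edge + .edge_density(Ri, rad[J[q]], d[q]) * rho * 2 * pi
        next
      }
      if (!is.null(res$empty) && res$empty) next  # circle fully covered
      segs <- res$arcs
      for (s in seq_len(nrow(segs))) {
        ph1 <- segs[s, 1L]; ph2 <- segs[s, 2L]
        dphi <- ph2 - ph1
        x1 <- o + rho * (u * cos(ph1) + v * sin(ph1))
        x2 <- o + rho * (u * cos(ph2) + v * sin(ph2))
        gb_arc <- gb_arc + costh[q] * dphi
        ## vector-area contribution, traversal from ph2 down to ph1
        cr <- c(o[2L] * (x1[3L] - x2[3L]) - o[3L] * (x1[2L] - x2[2L]),
                o[3L] * (x1[1L] - x2[1L]) - o[1L] * (x1[3L] - x2[3L]),
                o[1L] * (x1[2L] - x2[2L]) - o[2L] * (x1[1L] - x2[1L]))
        Svec <- Svec + 0.5 * (cr + rho^2 * (-dphi) * a)
        C_edge <- C_edge + .edge_density(Ri, rad[J[q]], d[q]) * rho * dphi
        n_arcs_open <- n_arcs_open + 1L
        arc_id <- length(arcs_i) + 1L
        arcs_i[[arc_id]] <- list(q = q, ph1 = ph1, ph2 = ph2,
                                 t1 = .circ_tangent(x1, o, a),
                                 t2 = .circ_tangent(x2, o, a),
                                 x1 = x1, x2 = x2)
        ## traversal: starts at x2 (ph2), ends at x1 (ph1)
        vert_pts <- rbind(vert_pts, x2, x1)
        vert_arc_start <- c(vert_arc_start, arc_id, NA)
        vert_arc_end <- c(vert_arc_end, NA, arc_id)
      }
    }
    ## if no boundary at all on this sphere but neighbors exist: sphere
    ## surface fully covered -> no contribution
    n_open_i <- length(arcs_i)
    if (n_open_i == 0L && full_circles == 0L) next

    ## match vertices (each 3D triple point appears once as an arc start and
    ## once as an arc end on this sphere)
    turn_sum <- 0
    n_vert_i <- 0L
    if (n_open_i > 0L) {
      np <- nrow(vert_pts)
      used <- rep(FALSE, np)
      pair_of <- integer(np)
      for (p1 in seq_len(np)) {
        if (used[p1]) next
        dd <- rowSums(sweep(vert_pts, 2L, vert_pts[p1, ], "-")^2)
        dd[p1] <- Inf
        dd[used] <- Inf
        p2 <- which.min(dd)
        if (!is.finite(dd[p2]) || dd[p2] > (1e-5 * Ri)^2)
          stop("internal error: unmatched boundary vertex in arrangement")
        used[p1] <- TRUE; used[p2] <- TRUE
        pair_of[p1] <- p2; pair_of[p2] <- p1
        n_vert_i <- n_vert_i + 1L
        ## one of the two is an arc end, the other an arc start
        aid_end <- c(vert_arc_end[p1], vert_arc_end[p2])
        aid_start <- c(vert_arc_start[p1], vert_arc_start[p2])
        a_in <- aid_end[!is.na(aid_end)][1L]
        a_out <- aid_start[!is.na(aid_start)][1L]
        if (is.na(a_in) || is.na(a_out))
          stop("internal error: inconsistent arc orientation at vertex")
        tin <- arcs_i[[a_in]]$t1   # tangent at arc end (ph1)
        tout <- arcs_i[[a_out]]$t2 # tangent at arc start (ph2)
        pt <- vert_pts[p1, ]
        nrm <- (pt - ci) / Ri
        cr <- c(tin[2L] * tout[3L] - tin[3L] * tout[2L],
                tin[3L] * tout[1L] - tin[1L] * tout[3L],
                tin[1L] * tout[2L] - tin[2L] * tout[1L])
        turn_sum <- turn_sum + atan2(sum(nrm * cr), sum(tin * tout))
      }
    }
    ## Euler characteristic of the exposed region of sphere i:
    ## chi = 2 - 2*(components of cap union) + (boundary curves)
    live <- seq_len(nn)
    parent <- live
    findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
    for (q1 in seq_len(nn - 1L)) for (q2 in (q1 + 1L):nn) {
      cosxi <- sum(axes[q1, ] * axes[q2, ])
      xi <- acos(pmin(pmax(cosxi, -1), 1))
      if (xi < theta[q1] + theta[q2]) {
        r1 <- findp(q1); r2 <- findp(q2)
        if (r1 != r2) parent[r1] <- r2
      }
    }
    cU <- length(unique(vapply(seq_len(nn), findp, 1L)))
    ## boundary curves: closed full circles + cycles of open arcs; with
    ## degree-2 vertices, #cycles = #arcs - #vertices + #components of the
    ## arc graph; each cycle has equal arc and vertex counts, so cycles =
    ## components of the endpoint-linkage graph
    b_cycles <- full_circles
    if (n_open_i > 0L) {
      ## union-find over arcs linked through shared vertices
      ap <- seq_len(n_open_i)
      finda <- function(x) { while (ap[x] != x) { ap[x] <<- ap[ap[x]]; x <- ap[x] }; x }
      np <- nrow(vert_pts)
      for (p1 in seq_len(np)) {
        p2 <- pair_of[p1]
        a1 <- if (!is.na(vert_arc_end[p1])) vert_arc_end[p1] else vert_arc_start[p1]
        a2 <- if (!is.na(vert_arc_end[p2])) vert_arc_end[p2] else vert_arc_start[p2]
        r1 <- finda(a1); r2 <- finda(a2)
        if (r1 != r2) ap[r1] <- r2
      }
      b_cycles <- b_cycles +
        length(unique(vapply(seq_len(n_open_i), finda, 1L)))
    }
    chi_i <- 2 - 2 * cU + b_cycles
    Ai <- Ri^2 * (2 * pi * chi_i + gb_arc - turn_sum)
    if (Ai < -1e-6 * Ri^2)
      stop("internal error: negative exposed area in arrangement")
    Ai <- max(Ai, 0)
    A <- A + Ai
    Asm <- Asm + Ai / Ri
    chi_sum <- chi_sum + chi_i
    n_vertices <- n_vertices + n_vert_i
    V <- V + (sum(ci * Svec) + Ri * Ai) / 3
  }
  Cm <- Asm + C_edge / 2    # each 3D edge was visited from both spheres
  Xm <- 2 * pi * (chi_sum - n_arcs_open / 2 + n_vertices / 3)
  out <- c(V = unname(V), A = unname(A), C = unname(Cm), X = unname(Xm))
  out
}

## mean-curvature line density of the reentrant edge between spheres with
## radii ri, rj at center distance d: -(1/2) * angle between outward normals
.edge_density <- function(ri, rj, d) {
  cg <- (ri^2 + rj^2 - d^2) / (2 * ri * rj)
  -0.5 * acos(pmin(pmax(cg, -1), 1))
}

## tangent of the boundary traversal (exposed side on the left) at point x
## on the circle with center o and axis a: t = (x - o) x a, normalized
.circ_tangent <- function(x, o, a) {
  r <- x - o
  t <- c(r[2L] * a[3L] - r[3L] * a[2L],
         r[3L] * a[1L] - r[1L] * a[3L],
         r[1L] * a[2L] - r[2L] * a[1L])
  t / sqrt(sum(t^2))
}

#' Steiner-series Monte-Carlo measures
#'
#' Stochastic backend for large unions: the volumes of the epsilon-parallel
#' bodies (all radii grown by epsilon) are estimated by seeded uniform
#' sampling in a common bounding box, and (V, A, C, X) are recovered by a
#' least-squares fit of the Steiner-type cubic
#' V(eps) = V + A*eps + C*eps^2 + (X/3)*eps^3.
#'
#' A single sample set serves all offsets (the signed distance to the union
#' is computed once per point), which makes successive V(eps) estimates
#' strongly correlated and the fitted differences far more precise than
#' independent estimates would be.  Because the parallel-body volume of a
#' non-convex union is not exactly polynomial in the offset, the fit
#' carries guard terms of one and two orders beyond the cubic whenever the
#' offset grid allows (quartic from six offsets, quintic from seven), and
#' the reported standard errors combine the binomial sampling covariance
#' with the successive-order coefficient shifts — an explicit estimate of
#' the truncation uncertainty.  With only four or five offsets a plain
#' cubic fit with sampling errors is all that is possible.
#'
#' For unions whose spheres interpenetrate deeply the curvature
#' coefficients recovered from the dilation series differ systematically
#' from the additive (convex-ring) measures the exact backend computes; see
#' the methods vignette.  V and A are free of this effect.
#'
#' @param spheres a [sphere_set].
#' @param epsilons increasing offsets in Angstrom; at least four distinct
#'   values including 0.
#' @param n_samples number of sample points (>= 1e5).
#' @param seed integer seed; identical seeds give bit-identical results.
#' @return A `measure_estimate`: list with `value` (named V, A, C, X),
#'   `standard_error`, `method`, `n_samples`, `seed`.
#' @export
measures_steiner_mc <- function(spheres, epsilons = seq(0, 0.8, length.out = 10),
                                n_samples = 1e6, seed = 1L) {
  stopifnot(inherits(spheres, "sphere_set"))
  epsilons <- sort(unique(as.numeric(epsilons)))
  if (length(epsilons) < 4L || !any(epsilons == 0) || any(epsilons < 0))
    stop("'epsilons' must hold >= 4 distinct non-negative offsets including 0")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1e5) stop("'n_samples' must be at least 1e5")
  ctr <- spheres$centers; rad <- spheres$radii
  emax <- max(epsilons)
  lo <- apply(ctr - (rad + emax), 2L, min)
  hi <- apply(ctr + (rad + emax), 2L, max)
  if (any(hi - lo <= 0)) stop("degenerate bounding box")
  vbox <- prod(hi - lo)
  ne <- length(epsilons)
  counts <- numeric(ne)
  with_seed(seed, {
    done <- 0L
    chunk <- 100000L
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      pts <- cbind(stats::runif(m, lo[1L], hi[1L]),
                   stats::runif(m, lo[2L], hi[2L]),
                   stats::runif(m, lo[3L], hi[3L]))
      ## signed distance to union: min_i (|x - c_i| - r_i)
      sd <- rep(Inf, m)
      for (i in seq_len(nrow(ctr))) {
        di <- sqrt((pts[, 1L] - ctr[i, 1L])^2 + (pts[, 2L] - ctr[i, 2L])^2 +
                   (pts[, 3L] - ctr[i, 3L])^2) - rad[i]
        sd <- pmin(sd, di)
      }
      for (e in seq_len(ne)) counts[e] <- counts[e] + sum(sd <= epsilons[e])
      done <- done + m
    }
  })
  p <- counts / n_samples
  Vhat <- vbox * p
  ## nested events: Cov(p_a, p_b) = p_min - p_a p_b
  pc <- outer(seq_len(ne), seq_len(ne), function(a, b) p[pmin(a, b)])
  cov_p <- (pc - outer(p, p)) / n_samples
  one_fit <- function(order) {
    Xd <- cbind(1, epsilons, epsilons^2, epsilons^3 / 3)
    if (order >= 4L) Xd <- cbind(Xd, epsilons^4)
    if (order >= 5L) Xd <- cbind(Xd, epsilons^5)
    xtx <- crossprod(Xd)
    if (kappa(xtx) > 1e13)
      stop("epsilon grid is ill-conditioned for the Steiner fit; spread the offsets")
    M <- solve(xtx, t(Xd))
    list(beta = drop(M %*% Vhat)[1:4],
         cov = (vbox^2 * (M %*% cov_p %*% t(M)))[1:4, 1:4])
  }
  f3 <- one_fit(3L)
  if (ne >= 7L) {
    f4 <- one_fit(4L)
    f5 <- one_fit(5L)
    beta <- f5$beta
    se <- sqrt(pmax(diag(f5$cov), 0) + (f5$beta - f4$beta)^2 +
               (f4$beta - f3$beta)^2)
  } else if (ne == 6L) {
    f4 <- one_fit(4L)
    beta <- f4$beta
    se <- sqrt(pmax(diag(f4$cov), 0) + (f4$beta - f3$beta)^2)
  } else {
    beta <- f3$beta
    se <- sqrt(pmax(diag(f3$cov), 0))
  }
  structure(list(value = stats::setNames(beta, morph_names),
                 standard_error = stats::setNames(se, morph_names),
                 method = "steiner_mc", n_samples = n_samples,
                 seed = as.integer(seed), epsilons = epsilons),
            class = "measure_estimate")
}

#' @export
print.measure_estimate <- function(x, ...) {
  cat(sprintf("<measure_estimate> method=%s  n=%s  seed=%s\n", x$method,
              format(x$n_samples), format(x$seed)))
  tab <- rbind(value = x$value, se = x$standard_error)
  print(signif(tab, 7))
  invisible(x)
}

#' Morphometric measures with probe dilation and backend dispatch
#'
#' Dilates the set by the probe radius and delegates to the exact or
#' stochastic backend.  `method = "auto"` chooses the exact arrangement
#' below `exact_limit` spheres and the Steiner Monte-Carlo estimator above.
#'
#' @param spheres a [sphere_set].
#' @param probe probe radius in Angstrom (half the solvent hard-sphere
#'   diameter; default 1.4).
#' @param method one of "auto", "exact", "steiner_mc".
#' @param exact_limit sphere-count limit for the exact backend.
#' @param tol degeneracy tolerance of the exact backend.
#' @param epsilons,n_samples,seed Steiner Monte-Carlo settings (ignored by
#'   the exact backend).
#' @return A `measure_estimate` (`standard_error` all zero for the exact
#'   backend).
#' @export
measures <- function(spheres, probe = 1.4, method = c("auto", "exact", "steiner_mc"),
                     exact_limit = 4000L, tol = 1e-8,
                     epsilons = seq(0, 0.8, length.out = 10),
                     n_samples = 1e6, seed = 1L) {
  method <- match.arg(method)
  dil <- dilate(spheres, probe)
  n <- nsphere(dil)
  if (method == "auto") method <- if (n <= exact_limit) "exact" else "steiner_mc"
  if (method == "exact") {
    val <- measures_exact(dil, tol = tol, max_spheres = exact_limit)
    structure(list(value = val,
                   standard_error = stats::setNames(rep(0, 4L), morph_names),
                   method = "exact", n_samples = 0L, seed = NA_integer_),
              class = "measure_estimate")
  } else {
    measures_steiner_mc(dil, epsilons = epsilons, n_samples = n_samples,
                        seed = seed)
  }
}

#' Evaluate an RNG-dependent expression under a fixed seed
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the prior
#' RNG state afterwards, so seeded operations never perturb a session's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
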