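#' Pressure protocol for an inflation test
#'
#' Ordered intraluminal pressure levels in mmHg. The first imaged state (10
#' mmHg in the default protocol) is taken as the reference configuration:
#' the geometry is treated as stress-free there and loads are applied as
#' gauge pressures above it. 1 mmHg = 0.133322 kPa.
#'
#' @param levels_mmHg Strictly increasing pressures (mmHg), first >= 0.
#' @param reference_mmHg Reference (imaging) pressure; defaults to the first
#'   level.
#' @return A `pressure_protocol` tibble with columns `mmHg` and `kPa_gauge`.
#' @export
pressure_protocol <- function(levels_mmHg = c(10, 80, 100, 120),
                              reference_mmHg = levels_mmHg[1]) {
  stopifnot(length(levels_mmHg) >= 1, levels_mmHg[1] >= 0,
            all(diff(levels_mmHg) > 0), reference_mmHg <= levels_mmHg[1])
  out <- tibble::tibble(
    mmHg = as.numeric(levels_mmHg),
    kPa_gauge = (as.numeric(levels_mmHg) - reference_mmHg) * MMHG_TO_KPA)
  structure(out, reference_mmHg = reference_mmHg,
            class = c("pressure_protocol", class(out)))
}

#' @export
MMHG_TO_KPA <- 0.133322

#' Neo-Hookean strain energy density (plane strain)
#'
#' `W = C (I1 - 3)` with `I1` the first invariant of the left Cauchy-Green
#' tensor under plane strain (out-of-plane stretch 1), evaluated for an
#' in-plane deformation gradient. The incompressibility constraint itself is
#' enforced by the solver's mixed (or penalty) formulation, not here.
#'
#' @param C Shear modulus parameter in kPa (> 0); the classical shear
#'   modulus is `mu = 2 C`.
#' @param F 2x2 in-plane deformation gradient with positive determinant.
#' @return Strain energy density in kPa.
#' @export
strain_energy_density <- function(C, F) {
  stopifnot(C > 0, is.matrix(F), all(dim(F) == c(2L, 2L)))
  if (det(F) <= 0) stop("non-positive Jacobian", call. = FALSE)
  I1 <- sum(F^2) + 1
  C * (I1 - 3)
}

#' Inflate a meshed plaque cross-section
#'
#' Plane-strain finite-element forward solve: incompressible Neo-Hookean
#' tissue (wall, intima, calcium) via a Taylor-Hood mixed
#' displacement-pressure formulation (or a near-incompressible penalty
#' fallback), a compressible Neo-Hookean buffer with zero Poisson ratio,
#' follower pressure on the deformed lumen boundary, zero displacement on
#' the buffer outer border, and Newton-Raphson with adaptive load stepping
#' and bisection on divergence.
#'
#' @param mesh A `plaque_mesh`.
#' @param materials A `material_map`.
#' @param protocol A `pressure_protocol` (or numeric mmHg levels).
#' @param solver_opts List; recognised entries `formulation` ("mixed" or
#'   "penalty"), `tol` (relative residual, default 1e-8), `max_it` (Newton
#'   iterations per step, default 25), `max_bisect` (default 8),
#'   `init_frac` (initial load step as a fraction of the largest target,
#'   default 0.2), `penalty_factor` (bulk modulus multiple of C for the
#'   penalty path, default 1e4).
#' @return List of `fe_solution` objects, one per protocol level, each with
#'   `pressure_mmHg`, `pressure_kPa` (gauge), nodal displacement matrix `U`
#'   (mm), pressure-like multiplier `p`, `converged`, `newton_iterations`.
#' @export
solve_inflation <- function(mesh, materials, protocol, solver_opts = list()) {
  stopifnot(inherits(mesh, "plaque_mesh"), inherits(materials, "material_map"))
  if (!inherits(protocol, "pressure_protocol")) protocol <- pressure_protocol(protocol)
  o <- utils::modifyList(list(formulation = "mixed", tol = 1e-8, max_it = 25L,
                              max_bisect = 8L, init_frac = 0.2,
                              penalty_factor = 1e4, chord = TRUE,
                              line_search = TRUE), solver_opts)
  if (o$formulation == "penalty" && is.null(solver_opts$line_search))
    o$line_search <- FALSE
  fe_setup_and_solve(mesh, materials, protocol$kPa_gauge, protocol$mmHg, o)
}

fe_material_vectors <- function(mesh, materials, formulation, penalty_factor) {
  Cmap <- c(wall = materials$C_wall, intima = materials$C_intima,
            calcium = materials$C_calcium, buffer = materials$C_buffer)
  Ce <- Cmap[as.character(mesh$region)]
  mu <- 2 * Ce
  tissue <- mesh$region != "buffer"
  if (formulation == "mixed") {
    incomp <- as.integer(tissue)
    lam <- rep(0, length(Ce))  # buffer: nu = 0 -> lambda = 0
  } else {
    incomp <- rep(0L, length(Ce))
    lam <- ifelse(tissue, penalty_factor * Ce, 0)
  }
  list(mu = unname(mu), lam = unname(lam), incomp = incomp)
}

# assemble the problem context: dof maps, materials, and a Newton closure
fe_make_context <- function(mesh, materials, o) {
  n <- nrow(mesh$nodes)
  mat <- fe_material_vectors(mesh, materials, o$formulation, o$penalty_factor)

  # pressure dofs: corner nodes touched by incompressible elements
  pidx <- integer(n)
  if (any(mat$incomp == 1L)) {
    pc <- unique(as.vector(mesh$tri[mat$incomp == 1L, 1:3]))
    pidx[pc] <- seq_along(pc)
  }
  n_pdof <- sum(pidx > 0L)
  ndof <- 2L * n + n_pdof

  fixed_u <- c(2L * mesh$fixed_nodes - 1L, 2L * mesh$fixed_nodes)
  free <- setdiff(seq_len(ndof), fixed_u)
  free_u <- free[free <= 2L * n]

  tri_i <- matrix(as.integer(mesh$tri), nrow(mesh$tri))
  edges_i <- matrix(as.integer(mesh$lumen_edges), nrow(mesh$lumen_edges))

  # modified Newton: the sparse LU factorization of the tangent is reused
  # across iterations (and load steps) while the residual keeps contracting,
  # and refreshed at the current state whenever progress stalls; convergence
  # is judged on the true residual, so the converged solution is identical
  # to a full Newton solve
  env <- new.env(parent = emptyenv())
  env$fac <- NULL

  # residual (and assembly triplets) at a state
  eval_state <- function(U, pv, P) {
    asm <- .fem_assemble(mesh$nodes, U, tri_i, mat$mu, mat$lam,
                         as.integer(mat$incomp), as.integer(pidx), pv, n_pdof)
    if (!asm$ok) return(NULL)
    fl <- .follower_load(mesh$nodes, U, edges_i, P, 2L * n)
    R <- asm$resid
    R[seq_len(2L * n)] <- R[seq_len(2L * n)] - fl$f
    rn <- sqrt(sum(R[free]^2))
    if (!is.finite(rn)) return(NULL)
    list(asm = asm, fl = fl, R = R, rn = rn,
         ref = max(sqrt(sum(fl$f[free_u]^2)), 1e-9))
  }

  newton <- function(U, pv, P) {
    res <- eval_state(U, pv, P)
    if (is.null(res)) return(list(ok = FALSE, U = U, pv = pv, its = 0L))
    rn_first <- res$rn
    # roundoff floor: with a large penalty modulus the achievable residual
    # is limited by cancellation; deep relative reduction counts as
    # converged when the nominal tolerance sits below that floor
    floor_ok <- function(r) !isTRUE(o$line_search) &&
      r$rn <= 1e-6 * max(r$ref, rn_first)
    total_it <- 0L
    rn_prev <- Inf
    age <- 1L        # iterations since the factorization was refreshed
    slow <- 0L       # consecutive weak contractions despite a fresh tangent
    force <- FALSE   # refactor demanded by a failed line search
    rn_hist <- rep(Inf, o$max_it + 1L)
    for (it in seq_len(o$max_it)) {
      if (res$rn <= o$tol * res$ref)
        return(list(ok = TRUE, U = U, pv = pv, its = total_it,
                    resid = res$rn / res$ref))
      rn_hist[it] <- res$rn
      # stagnation: healthy (even chord) Newton gains well over 10x per
      # five iterations; grinding steps are better served by a smaller
      # load increment, so give up early and let the bisection act
      if (it > 5L && res$rn > 0.1 * rn_hist[it - 5L])
        return(list(ok = floor_ok(res), U = U, pv = pv, its = total_it))
      stalled <- res$rn > 0.5 * rn_prev
      if (stalled && age == 0L) {
        slow <- slow + 1L
        if (slow > 6L) return(list(ok = FALSE, U = U, pv = pv, its = total_it))
      } else if (!stalled) slow <- 0L
      if (is.null(env$fac) || !isTRUE(o$chord) || force || (stalled && age > 0L)) {
        force <- FALSE
        K <- Matrix::sparseMatrix(
          i = c(res$asm$i, res$fl$i), j = c(res$asm$j, res$fl$j),
          x = c(res$asm$v, res$fl$v), dims = c(ndof, ndof))
        env$fac <- tryCatch(Matrix::lu(K[free, free, drop = FALSE]),
                            error = function(e) NULL)
        if (is.null(env$fac))
          return(list(ok = FALSE, U = U, pv = pv, its = total_it))
        age <- 0L
      } else age <- age + 1L
      dU <- tryCatch(as.numeric(Matrix::solve(env$fac, res$R[free])),
                     error = function(e) NULL)
      if (is.null(dU) || anyNA(dU) || any(!is.finite(dU)) ||
          max(abs(dU)) > 1e8) {
        env$fac <- NULL
        return(list(ok = FALSE, U = U, pv = pv, its = total_it))
      }
      full <- numeric(ndof); full[free] <- dU
      dUm <- matrix(full[seq_len(2L * n)], n, 2L, byrow = TRUE)
      dpv <- if (n_pdof > 0L) full[2L * n + seq_len(n_pdof)] else 0

      # backtracking line search on the residual norm; the penalty
      # formulation must overshoot (its quadratic constraint term inflates
      # the residual after a linear step before quadratic convergence sets
      # in), so there plain full steps are taken instead
      accepted <- FALSE
      for (s in c(1, 0.5, 0.25, 0.1)) {
        U_try <- U - s * dUm
        pv_try <- pv - s * dpv
        res_try <- eval_state(U_try, pv_try, P)
        if (!is.null(res_try) &&
            (!isTRUE(o$line_search) || res_try$rn < res$rn ||
               res_try$rn <= o$tol * res_try$ref)) {
          rn_prev <- res$rn
          U <- U_try; pv <- pv_try; res <- res_try
          accepted <- TRUE
          break
        }
      }
      total_it <- total_it + 1L
      if (!accepted) {
        if (age == 0L)  # even a fresh tangent gives no descent direction
          return(list(ok = floor_ok(res), U = U, pv = pv, its = total_it))
        force <- TRUE  # refactor at the current state and retry
        rn_prev <- Inf
      }
    }
    list(ok = floor_ok(res), U = U, pv = pv, its = total_it)
  }

  list(n = n, n_pdof = n_pdof, newton = newton, opts = o)
}

fe_initial_state <- function(ctx) {
  list(U = matrix(0, ctx$n, 2L),
       pv = if (ctx$n_pdof > 0L) numeric(ctx$n_pdof) else numeric(1L),
       P = 0, dP = NA_real_, its = 0L)
}

# continue a load path to each target (sorted ascending, all >= state$P);
# adaptive stepping with bisection on divergence; with on_fail = "partial"
# the targets reached before a divergence are returned (missing snapshots
# stay NULL and `failed_at` records the first unreached target)
fe_continue <- function(ctx, state, targets_kPa, on_fail = "error") {
  o <- ctx$opts
  out <- vector("list", length(targets_kPa))
  failed_at <- NA_real_
  Pspan <- max(max(targets_kPa) - state$P, 1e-12)
  if (is.na(state$dP)) state$dP <- max(o$init_frac * Pspan, 1e-12)
  # after a difficult stretch the adaptive step may be minuscule; restart
  # each call with a sane floor (bisection will shrink it again if needed)
  state$dP <- min(max(state$dP, 0.02 * Pspan), Pspan)
  for (tix in seq_along(targets_kPa)) {
    tgt <- targets_kPa[tix]
    if (tgt < state$P - 1e-9)
      stop("fe_continue: target below current load; restart the path", call. = FALSE)
    depth <- 0L
    spent <- 0L  # Newton iterations spent on this target (crawl guard)
    while (state$P < tgt - 1e-12) {
      P_try <- min(state$P + state$dP, tgt)
      st <- ctx$newton(state$U, state$pv, P_try)
      spent <- spent + max(st$its, 1L)
      if (st$ok) {
        state$U <- st$U; state$pv <- st$pv; state$P <- P_try
        state$its <- state$its + st$its
        if (st$its <= 5L) state$dP <- state$dP * 1.5
        depth <- 0L
      } else {
        state$dP <- state$dP / 2; depth <- depth + 1L
      }
      if (depth > o$max_bisect || spent > 40L * (o$max_bisect + 2L)) {
        if (on_fail == "partial") { failed_at <- tgt; break }
        stop("inflation solve did not converge at ", signif(P_try, 4),
             " kPa after ", o$max_bisect,
             " bisections; reduce the load step or refine the mesh",
             call. = FALSE)
      }
    }
    if (!is.na(failed_at)) break
    out[[tix]] <- list(U = state$U, pv = state$pv, P = state$P, its = state$its)
  }
  list(snapshots = out, state = state, failed_at = failed_at)
}

fe_setup_and_solve <- function(mesh, materials, loads_kPa, levels_mmHg, o) {
  ctx <- fe_make_context(mesh, materials, o)
  ord <- order(loads_kPa)
  cont <- fe_continue(ctx, fe_initial_state(ctx), loads_kPa[ord])
  results <- vector("list", length(loads_kPa))
  for (k in seq_along(ord)) {
    sn <- cont$snapshots[[k]]
    results[[ord[k]]] <- fe_solution(levels_mmHg[ord[k]], loads_kPa[ord[k]],
                                     sn$U, sn$pv, TRUE, sn$its, mesh)
  }
  results
}

fe_solution <- function(mmHg, kPa, U, pv, converged, its, mesh) {
  structure(list(pressure_mmHg = mmHg, pressure_kPa = kPa, U = U, p = pv,
                 converged = converged, newton_iterations = its,
                 n_nodes = nrow(mesh$nodes)),
            class = "fe_solution")
}

#' Analytic inflation of an incompressible Neo-Hookean tube (plane strain)
#'
#' One-dimensional verification oracle for the finite-element solver.
#' Kinematics of incompressible plane-strain tube inflation give
#' `r^2 = R^2 + a^2 - A^2`; radial equilibrium integrates to
#' `P = int_a^b 2 C (lambda^2 - lambda^-2) / r dr` with `lambda = r / R`.
#' The deformed inner radius `a` is found by root bracketing on the
#' monotone pressure-expansion relation.
#'
#' @param C Shear modulus parameter (kPa, > 0); either a scalar for a
#'   homogeneous tube or a length-2 vector `c(inner, outer)` for a
#'   two-layer tube with the interface at `interface_radius`.
#' @param inner_radius,outer_radius Reference radii (mm), `0 < inner < outer`.
#' @param P Luminal gauge pressure (kPa, >= 0).
#' @param interface_radius Reference radius of the layer interface (mm),
#'   required when `C` has length 2.
#' @return Deformed inner radius in mm.
#' @export
analytic_tube_inflation <- function(C, inner_radius, outer_radius, P,
                                    interface_radius = NULL) {
  stopifnot(all(C > 0), inner_radius > 0, outer_radius > inner_radius, P >= 0)
  A <- inner_radius; B <- outer_radius
  if (length(C) == 2L) {
    stopifnot(!is.null(interface_radius),
              interface_radius > A, interface_radius < B)
    bounds <- c(A, interface_radius, B)
  } else {
    bounds <- c(A, B)
  }
  pressure_of <- function(a) {
    if (a <= A) return(0)
    d <- a^2 - A^2
    g <- function(R, Ck) {
      r2 <- R^2 + d
      2 * Ck * (r2 / R^2 - R^2 / r2) * R / r2
    }
    sum(vapply(seq_along(C), function(k)
      stats::integrate(g, bounds[k], bounds[k + 1L], Ck = C[k],
                       rel.tol = 1e-10, abs.tol = 1e-12)$value, numeric(1)))
  }
  if (P == 0) return(A)
  hi <- A * 1.05
  while (pressure_of(hi) < P) {
    hi <- hi * 1.5
    if (hi > 100 * A) stop("no root in physical range", call. = FALSE)
  }
  stats::uniroot(function(a) pressure_of(a) - P, c(A, hi), tol = 1e-10)$root
}

#' Locate points in a plaque mesh
#'
#' Structured radial--angular point location with a brute-force fallback.
#'
#' @param mesh A `plaque_mesh`.
#' @param points n x 2 matrix (mm).
#' @param extrapolate If `TRUE`, points outside the mesh are assigned their
#'   nearest element with unclamped barycentric coordinates; otherwise an
#'   error is raised.
#' @return List with integer `elem`, matrix `bary` (n x 3) and logical
#'   `outside`.
#' @export
locate_points <- function(mesh, points, extrapolate = FALSE) {
  points <- matrix(points, ncol = 2L)
  np <- nrow(points)
  nr <- mesh$nr; nth <- mesh$n_theta
  dthe <- 2 * pi / nth
  elem <- integer(np); bary <- matrix(0, np, 3L); outside <- logical(np)

  bary_of <- function(e, pt) {
    i1 <- mesh$tri[e, 1L]; i2 <- mesh$tri[e, 2L]; i3 <- mesh$tri[e, 3L]
    v1 <- mesh$nodes[i1, ]; v2 <- mesh$nodes[i2, ]; v3 <- mesh$nodes[i3, ]
    Tm <- cbind(v1 - v3, v2 - v3)
    l <- solve(Tm, pt - v3)
    c(l[1], l[2], 1 - l[1] - l[2])
  }
  elems_of_quad <- function(j, k) {
    base <- 2L * ((j - 1L) * (nr - 1L) + (k - 1L))
    c(base + 1L, base + 2L)
  }

  for (p in seq_len(np)) {
    pt <- points[p, ]
    dxy <- pt - mesh$center
    r <- sqrt(sum(dxy^2)); th <- atan2(dxy[2], dxy[1]) %% (2 * pi)
    j <- as.integer(th %/% dthe) + 1L
    jn <- if (j == nth) 1L else j + 1L
    s <- (th - (j - 1L) * dthe) / dthe
    rloc <- mesh$rad[, j] * (1 - s) + mesh$rad[, jn] * s
    k0 <- findInterval(r, rloc)
    found <- FALSE
    for (k in unique(pmax(1L, pmin(nr - 1L, k0 + c(0L, -1L, 1L))))) {
      for (e in elems_of_quad(j, k)) {
        b <- bary_of(e, pt)
        if (all(b >= -1e-9)) { elem[p] <- e; bary[p, ] <- b; found <- TRUE; break }
      }
      if (found) break
    }
    if (!found) {
      # brute force over the neighbouring sectors
      js <- unique(((j - 2L):(j + 1L)) %% nth + 1L)
      cand <- unlist(lapply(js, function(jj) {
        base <- 2L * ((jj - 1L) * (nr - 1L))
        base + seq_len(2L * (nr - 1L))
      }))
      best <- NULL; best_min <- -Inf
      for (e in cand) {
        b <- bary_of(e, pt)
        mb <- min(b)
        if (mb >= -1e-9) { best <- list(e, b); best_min <- mb; break }
        if (mb > best_min) { best <- list(e, b); best_min <- mb }
      }
      if (best_min >= -1e-9) {
        elem[p] <- best[[1L]]; bary[p, ] <- best[[2L]]
      } else if (extrapolate) {
        elem[p] <- best[[1L]]; bary[p, ] <- best[[2L]]; outside[p] <- TRUE
      } else {
        stop("point (", pt[1], ", ", pt[2], ") outside the meshed domain",
             call. = FALSE)
      }
    }
  }
  list(elem = elem, bary = bary, outside = outside)
}

#' Interpolate a finite-element displacement field
#'
#' Quadratic shape-function interpolation of nodal displacements; exact at
#' nodes.
#'
#' @param solution An `fe_solution`.
#' @param mesh The `plaque_mesh` the solution was computed on.
#' @param points n x 2 matrix of query points (mm).
#' @inheritParams locate_points
#' @return n x 2 matrix of displacements (mm).
#' @export
interpolate_displacement <- function(solution, mesh, points, extrapolate = FALSE) {
  U <- if (inherits(solution, "fe_solution")) solution$U else solution
  loc <- locate_points(mesh, points, extrapolate = extrapolate)
  .p2_interp(U, matrix(as.integer(mesh$tri), nrow(mesh$tri)),
             as.integer(loc$elem), loc$bary)
}
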