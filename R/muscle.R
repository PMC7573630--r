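# Hill-type muscle-tendon dynamics in implicit form. The contraction state
# is s, the projection of the CE length on the muscle line of action, which
# keeps the residual and its partials finite as the pennation angle
# approaches pi/2 (constant muscle height h = l_CE_opt * sin(phi_opt)).

#' Construct a muscle-tendon path polynomial
#'
#' A path polynomial maps joint angles to muscle-tendon length
#' `l_MTU(q) = sum_t coef_t * prod_j q_j^pow_tj`; moment arms follow from
#' the virtual-work convention as `-d l_MTU / d q_j`.
#'
#' @param dof_names character vector of spanned DOF names
#' @param terms list of terms, each `list(coef =, dofs =, powers =)` with
#'   `dofs` a subset of `dof_names` and `powers` matching positive integers
#' @return a `runopt_path` object
#' @export
path_polynomial <- function(dof_names, terms) {
  for (tm in terms) {
    stopifnot(is.numeric(tm$coef), length(tm$dofs) == length(tm$powers))
    if (!all(tm$dofs %in% dof_names)) stop("term references unknown DOF")
    if (length(tm$powers) && sum(tm$powers) > 4)
      stop("total term degree must be <= 4")
  }
  structure(list(dof_names = dof_names, terms = terms),
            class = "runopt_path")
}

#' Muscle-tendon length and moment arms
#'
#' Evaluates the path polynomial and its negated gradient.
#'
#' @param path a `runopt_path` (or the `path` element of a model muscle)
#' @param q named numeric vector covering the path's DOFs (or positional in
#'   the order of `path$dof_names`)
#' @return list with `l_mtu` (m) and `moment_arms` (named, m)
#' @export
mtu_geometry <- function(path, q) {
  if (is.null(names(q))) names(q) <- path$dof_names
  stopifnot(all(path$dof_names %in% names(q)))
  l <- 0
  darm <- setNames(numeric(length(path$dof_names)), path$dof_names)
  for (tm in path$terms) {
    val <- tm$coef
    for (k in seq_along(tm$dofs)) val <- val * q[[tm$dofs[k]]]^tm$powers[k]
    l <- l + val
    for (k in seq_along(tm$dofs)) {
      der <- tm$coef * tm$powers[k] * q[[tm$dofs[k]]]^(tm$powers[k] - 1)
      for (k2 in seq_along(tm$dofs)) {
        if (k2 != k) der <- der * q[[tm$dofs[k2]]]^tm$powers[k2]
      }
      darm[tm$dofs[k]] <- darm[tm$dofs[k]] + der
    }
  }
  list(l_mtu = as.numeric(l), moment_arms = -darm)
}

# all monomials of total degree <= max_degree over nd variables
monomial_exponents <- function(nd, max_degree) {
  grid <- do.call(expand.grid, rep(list(0:max_degree), nd))
  grid <- grid[rowSums(grid) <= max_degree, , drop = FALSE]
  grid <- grid[order(rowSums(grid)), , drop = FALSE]
  as.matrix(grid)
}

#' Fit a path polynomial to length samples
#'
#' Least-squares fit of all monomials of total degree up to `max_degree`
#' over the spanned DOFs; noise-free data generated by a polynomial of that
#' class is recovered to machine precision.
#'
#' @param samples list of `list(q =, l_mtu =)` pairs, `q` named
#' @param dof_names DOFs spanned by the path
#' @param max_degree maximum total polynomial degree
#' @return a `runopt_path` with an `rms_residual` attribute (m)
#' @export
fit_path_polynomial <- function(samples, dof_names, max_degree = 2) {
  nd <- length(dof_names)
  expo <- monomial_exponents(nd, max_degree)
  if (length(samples) < nrow(expo))
    stop("need at least ", nrow(expo), " samples for ", nrow(expo),
         " monomials; consider a lower degree")
  Q <- do.call(rbind, lapply(samples,
                             function(s) as.numeric(s$q[dof_names])))
  y <- vapply(samples, `[[`, numeric(1), "l_mtu")
  A <- vapply(seq_len(nrow(expo)), function(i) {
    apply(Q, 1, function(row) prod(row^expo[i, ]))
  }, numeric(length(y)))
  A <- matrix(A, nrow = length(y))
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A))
    stop("rank-deficient design matrix; sample more poses or lower the ",
         "degree")
  coefs <- qr.coef(qr_A, y)
  resid <- y - A %*% coefs
  terms <- lapply(seq_len(nrow(expo)), function(i) {
    e <- expo[i, ]
    nz <- which(e > 0)
    list(coef = unname(coefs[i]), dofs = dof_names[nz],
         powers = as.integer(e[nz]))
  })
  out <- path_polynomial(dof_names, terms)
  attr(out, "rms_residual") <- sqrt(mean(resid^2))
  out
}

hill_curves <- function(p) {
  s0 <- (1 + 1 / p$A_hill) / p$v_max
  c_ecc <- (p$f_ecc - 1) / s0
  list(
    f_l = function(lce_rel) exp(-((lce_rel - 1) / p$W)^2),
    f_v = function(v_rel) {
      ifelse(v_rel < 0,
             (p$v_max + v_rel) / (p$v_max - v_rel / p$A_hill),
             (p$f_ecc * v_rel + c_ecc) / (v_rel + c_ecc))
    }
  )
}

#' Implicit Hill contraction residual
#'
#' Force balance along the muscle line of action with the projected CE
#' length `s` as contraction state: with constant muscle height
#' `h = l_CE_opt sin(phi_opt)`, the CE length is `sqrt(s^2 + h^2)` and the
#' residual is `F_SEE - (a F_ISO f_L f_V + F_PEE + d_CE v_CE) cos(phi)`.
#' The residual is strictly monotone in `sdot` (CE damping), so
#' `residual = 0` defines the contraction rate implicitly.
#'
#' @param p muscle parameter list (e.g. an element of `model$muscles`)
#' @param a activation in `[0, 1]`
#' @param s projected CE length (m), must be positive
#' @param sd rate of `s` (m/s)
#' @param l_mtu muscle-tendon length (m)
#' @return list with `residual` (N) and `F_SEE` (tendon force, N)
#' @export
contraction_residual <- function(p, a, s, sd, l_mtu) {
  if (any(s <= 0)) stop("contraction state s must be positive")
  h <- p$l_CE_opt * sin(p$phi_opt)
  l_ce <- sqrt(s^2 + h^2)
  cos_phi <- s / l_ce
  v_rel <- sd * cos_phi / p$l_CE_opt
  eps <- (l_mtu - s - p$l_slack) / p$l_slack
  f_see <- ifelse(eps > 0, p$F_ISO * (eps / p$eps0_SEE)^2, 0)
  stretch <- l_ce / p$l_CE_opt - 1
  f_pee <- ifelse(stretch > 0, p$k_PEE * p$F_ISO * stretch^2, 0)
  curves <- hill_curves(p)
  f_active <- a * p$F_ISO * curves$f_l(l_ce / p$l_CE_opt) * curves$f_v(v_rel)
  f_damp <- p$d_CE * p$F_ISO * v_rel
  list(residual = f_see - (f_active + f_pee + f_damp) * cos_phi,
       F_SEE = f_see)
}

#' Implicit activation dynamics residual
#'
#' First-order activation dynamics with a smooth excitation-weighted blend
#' of activation and deactivation rates:
#' `residual = adot - (n_e - a) (n_e / T_act + (1 - n_e) / T_deact)`.
#'
#' @param p muscle parameter list
#' @param a activation in `[0, 1]`
#' @param ad activation rate (1/s)
#' @param n_e neural excitation in `[0, 1]`
#' @return residual (1/s)
#' @export
activation_residual <- function(p, a, ad, n_e) {
  ad - (n_e - a) * (n_e / p$T_act + (1 - n_e) / p$T_deact)
}
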