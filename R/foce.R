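# FOCE-I marginal likelihood machinery.
#
# The engine works on a generic subject-level nonlinear model
#   y_j = f_j(eta) * (1 + eps1) + eps2,   eta ~ N(0, Omega)
# supplied as a callback returning predictions (and their Jacobian with
# respect to eta) for all observations at once; subjects are handled
# simultaneously through vectorized 1x1/2x2 Newton solves, which keeps
# the inner conditional-mode search fast enough to sit inside an outer
# quasi-Newton parameter search in pure R.
#
# Conventions:
#  * the per-subject penalized deviance minimized by the inner step is
#      q_i(eta) = sum_j [ (y_j - f_j)^2 / v_j + log v_j ] + eta' Omega^-1 eta
#    with v_j = sigma2_prop * f_j(eta)^2 + sigma2_add under interaction
#    (FOCE-I), or v_j evaluated at f_j(0) for plain FOCE;
#  * the objective function value (OFV) reported is -2 times the Laplace
#    (Gauss-Newton curvature) approximation of the log marginal
#    likelihood INCLUDING the sum(log 2*pi) constant, so absolute values
#    differ from NONMEM's convention by n_obs*log(2*pi) while OFV
#    differences match.

rowsum_vec <- function(x, g, n) {
  out <- rowsum(x, g)
  if (is.matrix(x)) out else as.vector(out)
}

# Closed-form one-compartment prediction callback for a dataset design.
# eta is an n_sub x 2 matrix (log-scale perturbations of CL and V).
# Observations with uniform dose histories use the geometric
# multiple-dose form
#   C = a r [ e^{-ke s} (1-Ee^k)/(1-Ee) - e^{-ka s} (1-Ea^k)/(1-Ea) ],
# with s the time since the last of k doses and Ee/Ea the per-interval
# decay factors; irregular histories use explicit superposition. An
# elimination rate within 1e-9 of ka is nudged off the removable
# singularity (never reached at escitalopram-like parameters).
pk_eta_model <- function(design, cl_base, v_base, ka) {
  n_obs <- design$n_obs
  ui <- design$uni_idx
  usub <- design$uni_sub
  uk <- design$uni_k; us <- design$uni_s
  utau <- design$uni_tau; uamt <- design$uni_amt
  pobs <- design$pair_obs
  psub <- design$pair_sub
  dt <- design$pair_dt
  amt <- design$pair_amt
  has_pairs <- length(pobs) > 0
  force(cl_base); force(v_base); force(ka)
  function(eta, deriv = TRUE) {
    cl <- cl_base * exp(eta[, 1])
    v <- v_base * exp(eta[, 2])
    ke_s <- cl / v
    near <- abs(ka - ke_s) < 1e-9 * ka
    if (any(near)) ke_s[near] <- ka * (1 - 1e-9)
    f <- numeric(n_obs)
    J1 <- numeric(n_obs)
    J2 <- numeric(n_obs)
    if (length(ui)) {
      ke <- ke_s[usub]
      a <- 1000 * uamt / v[usub]
      r <- ka / (ka - ke)
      xe <- exp(-ke * utau)
      Se <- (1 - xe^uk) / (1 - xe)
      ue <- exp(-ke * us) * Se
      xa <- exp(-ka * utau)
      ua <- exp(-ka * us) * (1 - xa^uk) / (1 - xa)
      cu <- a * r * (ue - ua)
      f[ui] <- cu
      if (deriv) {
        dSdx <- (Se - uk * xe^(uk - 1)) / (1 - xe)
        due <- -us * ue + exp(-ke * us) * dSdx * (-utau * xe)
        dke <- a * (r / (ka - ke) * (ue - ua) + r * due)
        J1[ui] <- dke * ke
        J2[ui] <- -cu - dke * ke
      }
    }
    if (has_pairs) {
      ke <- ke_s[psub]
      a <- 1000 * amt / v[psub]
      de <- ka - ke
      E1 <- exp(-ke * dt)
      EA <- exp(-ka * dt)
      r <- ka / de
      term <- a * r * (E1 - EA)
      if (!deriv) {
        fp <- rowsum(term, pobs)
        f[as.integer(rownames(fp))] <- fp[, 1]
      } else {
        Tke <- a * r * ((E1 - EA) / de - dt * E1)
        g1 <- Tke * ke
        M <- rowsum(cbind(term, g1), pobs)
        rows <- as.integer(rownames(M))
        f[rows] <- M[, 1]
        J1[rows] <- M[, 2]
        J2[rows] <- -M[, 1] - M[, 2]
      }
    }
    if (!deriv) return(list(f = f))
    list(f = f, J = cbind(J1, J2))
  }
}

# Conditional-mode (empirical Bayes) search, vectorized across subjects.
# Returns eta (n_sub x q), the per-subject penalized deviance, gradient
# norms, convergence flags, and the Gauss-Newton information needed for
# the Laplace determinant.
foce_inner <- function(model, y, obs_sub, n_sub, Omega, s2p, s2a,
                       interaction = TRUE, eta = NULL,
                       gtol = 1e-8, maxit = 100L) {
  q <- nrow(Omega)
  if (q > 2) stop("foce_inner supports at most 2 random effects")
  Oinv <- solve(Omega)
  if (is.null(eta)) eta <- matrix(0, n_sub, q)
  f0 <- NULL
  if (!interaction) f0 <- model(matrix(0, n_sub, q), deriv = FALSE)$f

  obs_var <- function(f) {
    fv <- if (interaction) f else f0
    pmax(s2p * fv^2 + s2a, 1e-12)
  }
  eval_obj <- function(eta) {
    f <- model(eta, deriv = FALSE)$f
    res <- y - f
    varv <- obs_var(f)
    dev <- res^2 / varv + log(varv)
    rowsum_vec(dev, obs_sub, n_sub) + rowSums((eta %*% Oinv) * eta)
  }
  eval_full <- function(eta) {
    mo <- model(eta, deriv = TRUE)
    f <- mo$f; J <- mo$J[, seq_len(q), drop = FALSE]
    res <- y - f
    varv <- obs_var(f)
    dev <- res^2 / varv + log(varv)
    obj <- rowsum_vec(dev, obs_sub, n_sub) + rowSums((eta %*% Oinv) * eta)
    w <- if (interaction) {
      -2 * res / varv - 2 * s2p * f * res^2 / varv^2 + 2 * s2p * f / varv
    } else {
      -2 * res / varv
    }
    grad <- rowsum_vec(w * J, obs_sub, n_sub) + 2 * (eta %*% Oinv)
    if (q == 1L) {
      A <- cbind(rowsum_vec(J[, 1]^2 / varv, obs_sub, n_sub))
    } else {
      A <- rowsum_vec(cbind(J[, 1]^2, J[, 1] * J[, 2], J[, 2]^2) / varv,
                      obs_sub, n_sub)
    }
    list(obj = obj, f = f, J = J, res = res, varv = varv,
         grad = grad, A = A)
  }
  newton_step <- function(grad, A, lam) {
    if (q == 1L) {
      h <- 2 * (Oinv[1, 1] + A[, 1]) + lam
      return(cbind(grad[, 1] / h))
    }
    h11 <- 2 * (Oinv[1, 1] + A[, 1]) + lam
    h12 <- 2 * (Oinv[1, 2] + A[, 2])
    h22 <- 2 * (Oinv[2, 2] + A[, 3]) + lam
    det <- pmax(h11 * h22 - h12^2, 1e-300)
    cbind((h22 * grad[, 1] - h12 * grad[, 2]) / det,
          (h11 * grad[, 2] - h12 * grad[, 1]) / det)
  }

  row_absmax <- function(M)
    do.call(pmax, lapply(seq_len(ncol(M)), function(k) abs(M[, k])))
  run_phase <- function(eta, maxit) {
    # Levenberg-Marquardt damped Gauss-Newton with backtracking. When a
    # subject's undamped step fails the (noise-tolerant) descent test
    # its damping is inflated, bending the step toward steepest descent
    # where the dropped interaction curvature terms mislead the
    # Gauss-Newton direction; damping decays again after clean full
    # steps. Subjects driven past lam = 1e8 are frozen (their remaining
    # gradient is below any resolvable objective change).
    n <- nrow(eta)
    st <- eval_full(eta)
    lam <- rep(0, n)
    frozen <- rep(FALSE, n)
    for (it in seq_len(maxit)) {
      gn <- row_absmax(st$grad)
      done <- frozen | gn < gtol
      if (all(done)) break
      step <- newton_step(st$grad, st$A, lam)
      t <- as.numeric(!done)
      eta_new <- eta
      ok <- done
      full_step <- rep(FALSE, n)
      for (ls in 1:9) {
        cand <- eta - step * t
        cand[ok, ] <- eta_new[ok, , drop = FALSE]
        obj_try <- eval_obj(cand)
        imp <- obj_try <= st$obj + 1e-10
        newly <- !ok & imp
        if (any(newly)) {
          rows <- which(newly)
          eta_new[rows, ] <- cand[rows, , drop = FALSE]
          full_step[rows] <- ls == 1L
        }
        ok <- ok | newly
        if (all(ok)) break
        t[!ok] <- t[!ok] / 2
      }
      fail <- !ok
      lam[fail] <- pmax(lam[fail] * 10, 1)
      lam[full_step] <- lam[full_step] / 10
      lam[lam < 1e-8] <- 0
      frozen <- frozen | (fail & lam > 1e8)
      if (max(row_absmax(eta_new - eta)) == 0 && !any(fail)) break
      eta <- eta_new
      st <- eval_full(eta)
    }
    # Exact-Newton polish judged on the analytic gradient norm (which
    # is free of objective round-off): the true inner Hessian is taken
    # as a central finite difference of the analytic gradient (the
    # Gauss-Newton matrix drops interaction curvature terms and stops
    # converging around |grad| ~ 1e-5), driving the conditional modes
    # to near machine precision so the OFV is a smooth,
    # warm-start-independent function of the population parameters.
    gn <- row_absmax(st$grad)
    if (any(gn > 1e-11)) {
      hh <- 1e-5
      Hc <- vector("list", q)
      for (k in seq_len(q)) {
        ep <- eta; ep[, k] <- ep[, k] + hh
        em <- eta; em[, k] <- em[, k] - hh
        Hc[[k]] <- (eval_full(ep)$grad - eval_full(em)$grad) / (2 * hh)
      }
      if (q == 1L) {
        th11 <- Hc[[1]][, 1]
        bad <- th11 <= 0
      } else {
        th11 <- Hc[[1]][, 1]
        th22 <- Hc[[2]][, 2]
        th12 <- (Hc[[1]][, 2] + Hc[[2]][, 1]) / 2
        tdet <- th11 * th22 - th12^2
        bad <- !(th11 > 0 & tdet > 0)
      }
      true_step <- function(grad) {
        s <- if (q == 1L) cbind(grad[, 1] / th11)
        else cbind((th22 * grad[, 1] - th12 * grad[, 2]) / tdet,
                   (th11 * grad[, 2] - th12 * grad[, 1]) / tdet)
        if (any(bad)) {
          s_gn <- newton_step(grad, st$A, rep(0, n))
          s[bad, ] <- s_gn[bad, , drop = FALSE]
        }
        s
      }
      tpol <- rep(1, n)
      for (it in 1:12) {
        act <- gn > 1e-11 & tpol > 1e-4
        if (!any(act)) break
        step <- true_step(st$grad)
        sn <- row_absmax(step)
        sc <- ifelse(sn * tpol > 0.5, 0.5 / sn, tpol)  # cap runaway steps
        cand <- eta - step * (sc * as.numeric(act))
        st_try <- eval_full(cand)
        gn_try <- row_absmax(st_try$grad)
        better <- act & gn_try < gn
        tpol[better] <- pmin(1, tpol[better] * 2)
        tpol[act & !better] <- tpol[act & !better] / 4
        if (any(better)) eta[better, ] <- cand[better, , drop = FALSE]
        st <- eval_full(eta)
        gn <- row_absmax(st$grad)
      }
    }
    list(eta = eta, st = st, gn = gn)
  }

  accept_tol <- max(gtol, 1e-3)
  ph <- run_phase(eta, maxit)
  if (any(ph$gn >= accept_tol) && any(eta != 0)) {
    # restart unconverged subjects from the origin
    eta2 <- ph$eta
    bad <- ph$gn >= accept_tol
    eta2[bad, ] <- 0
    ph2 <- run_phase(eta2, maxit)
    take <- ph2$st$obj <= ph$st$obj
    if (any(take)) {
      etam <- ph$eta
      etam[take, ] <- ph2$eta[take, , drop = FALSE]
      ph <- run_phase(etam, maxit)
    }
  }
  # a residual gradient below 1e-3 moves eta by < ~1e-4 and the OFV by
  # far less than the outer convergence tolerance: treat as converged
  list(eta = ph$eta, obj = ph$st$obj, f = ph$st$f, J = ph$st$J,
       res = ph$st$res, varv = ph$st$varv, A = ph$st$A,
       grad_norm = ph$gn, converged = ph$gn < accept_tol)
}

# OFV assembly from a converged inner state: the Laplace/FOCE-I
# approximate -2 log marginal likelihood including the log(2*pi) terms.
ofv_from_inner <- function(inner, Omega, obs_sub, n_sub) {
  q <- nrow(Omega)
  Oinv <- solve(Omega)
  ldetO <- as.numeric(determinant(Omega, logarithm = TRUE)$modulus)
  k_i <- tabulate(obs_sub, n_sub)
  if (q == 1L) {
    detB <- Oinv[1, 1] + inner$A[, 1]
  } else {
    detB <- (Oinv[1, 1] + inner$A[, 1]) * (Oinv[2, 2] + inner$A[, 3]) -
      (Oinv[1, 2] + inner$A[, 2])^2
  }
  ldetB <- ifelse(detB > 0, log(detB), Inf)
  per_sub <- inner$obj + k_i * log(2 * pi) + ldetO + ldetB
  list(ofv = sum(per_sub), per_subject = per_sub, inner = inner)
}

# Laplace/FOCE-I approximate -2 log marginal likelihood for a generic
# model callback (reference R engine).
foce_marginal_ofv <- function(model, y, obs_sub, n_sub, Omega, s2p, s2a,
                              interaction = TRUE, eta_start = NULL,
                              gtol = 1e-8, maxit = 100L) {
  inner <- foce_inner(model, y, obs_sub, n_sub, Omega, s2p, s2a,
                      interaction = interaction, eta = eta_start,
                      gtol = gtol, maxit = maxit)
  ofv_from_inner(inner, Omega, obs_sub, n_sub)
}

# Inner search for the PK model: compiled engine by default, with the
# generic R engine available for cross-checking.
pk_inner <- function(design, cl_base, v_base, ka, Omega, s2p, s2a,
                     interaction = TRUE, eta_start = NULL, gtol = 1e-8,
                     maxit = 100L, use_cpp = TRUE) {
  if (use_cpp) {
    .foce_inner_pk(design, as.numeric(cl_base), as.numeric(v_base), ka,
                   Omega, s2p, s2a, interaction, eta_start, gtol,
                   as.integer(maxit))
  } else {
    model <- pk_eta_model(design, cl_base, v_base, ka)
    foce_inner(model, design$y, design$obs_sub, design$n_sub, Omega,
               s2p, s2a, interaction = interaction, eta = eta_start,
               gtol = gtol, maxit = maxit)
  }
}

# PK-model OFV: inner search plus Laplace assembly.
pk_marginal_ofv <- function(design, cl_base, v_base, ka, Omega, s2p,
                            s2a, interaction = TRUE, eta_start = NULL,
                            gtol = 1e-8, maxit = 100L, use_cpp = TRUE) {
  inner <- pk_inner(design, cl_base, v_base, ka, Omega, s2p, s2a,
                    interaction = interaction, eta_start = eta_start,
                    gtol = gtol, maxit = maxit, use_cpp = use_cpp)
  ofv_from_inner(inner, Omega, design$obs_sub, design$n_sub)
}

# Baseline (eta = 0) individual parameters implied by a pk_params object
# for every subject in a dataset.
params_baseline <- function(params, subjects) {
  n <- nrow(subjects)
  g_age <- rep(1, n)
  if (params$theta_age != 0) {
    ages <- subject_covariate(subjects, "AGE")
    e <- linear_cov_effect(ages, params$theta_age, params$age_center,
                           sign = if (params$age_decreasing) -1 else 1,
                           floor = params$cov_floor, warn = FALSE)
    g_age <- as.numeric(e)
  }
  g_ph <- rep(1, n)
  if (params$theta_im != 1 || params$theta_pm != 1) {
    if (!("PHENOTYPE" %in% names(subjects)))
      stop("dataset lacks PHENOTYPE/CYP2C19 needed by the parameter set")
    g_ph <- phenotype_multiplier(subjects$PHENOTYPE,
                                 params$theta_im, params$theta_pm)
  }
  list(cl_base = params$tvcl * g_age * g_ph,
       v_base = rep(params$tvv, n))
}

#' Empirical-Bayes random effects at fixed population parameters
#'
#' Finds, for every subject, the conditional mode of the random effects
#' (eta_cl, eta_v) given the data and a population parameter set, by
#' minimizing the FOCE-I penalized deviance
#' `sum_j [(y_j - f_j(eta))^2 / v_j(eta) + log v_j(eta)] + eta' Omega^-1 eta`
#' with `v_j = sigma2_prop * f_j(eta)^2 + sigma2_add` evaluated at the
#' conditional prediction (the eta-epsilon interaction).
#'
#' @param data A [pk_dataset()].
#' @param params A [pk_params()] population parameter set with positive
#'   variances.
#' @param interaction Use the FOCE-I interaction residual variance
#'   (default) or plain FOCE (variance at the typical prediction).
#' @param gtol Gradient tolerance of the inner Newton search.
#' @return A data frame with columns `ID`, `eta_cl`, `eta_v`,
#'   `converged`; the per-subject Gauss-Newton curvature of the
#'   penalized deviance at the mode is attached as attribute
#'   `"hessian"` (one 2x2 matrix per subject).
#' @export
conditional_eta <- function(data, params, interaction = TRUE, gtol = 1e-8) {
  stopifnot(inherits(data, "pk_dataset"))
  validate_pk_params(params)
  if (params$omega2_cl <= 0 || params$omega2_v <= 0)
    stop("conditional_eta requires positive omega2 variances")
  design <- build_design(data)
  base <- params_baseline(params, data$subjects)
  Omega <- diag(c(params$omega2_cl, params$omega2_v))
  inner <- pk_inner(design, base$cl_base, base$v_base, params$ka,
                    Omega, params$sigma2_prop, params$sigma2_add,
                    interaction = interaction, gtol = gtol)
  Oinv <- solve(Omega)
  H <- lapply(seq_len(design$n_sub), function(i) {
    2 * (Oinv + matrix(c(inner$A[i, 1], inner$A[i, 2],
                         inner$A[i, 2], inner$A[i, 3]), 2, 2))
  })
  out <- data.frame(ID = data$subjects$ID,
                    eta_cl = inner$eta[, 1],
                    eta_v = inner$eta[, 2],
                    converged = inner$converged)
  attr(out, "hessian") <- H
  out
}

#' FOCE-I objective function value at fixed parameters
#'
#' Evaluates -2 times the Laplace (FOCE-I) approximate log marginal
#' likelihood of a dataset at a given population parameter set, at the
#' empirical-Bayes modes. The `sum(log 2*pi)` constant is included, so
#' absolute values are offset from NONMEM's convention by
#' `n_obs * log(2*pi)` while differences between nested models (delta
#' OFV) are directly comparable.
#'
#' @inheritParams conditional_eta
#' @return The OFV (numeric scalar) with attribute `"per_subject"`.
#' @export
foce_ofv <- function(data, params, interaction = TRUE) {
  stopifnot(inherits(data, "pk_dataset"))
  validate_pk_params(params)
  design <- build_design(data)
  base <- params_baseline(params, data$subjects)
  Omega <- diag(c(params$omega2_cl, params$omega2_v))
  res <- pk_marginal_ofv(design, base$cl_base, base$v_base, params$ka,
                         Omega, params$sigma2_prop, params$sigma2_add,
                         interaction = interaction)
  structure(res$ofv, per_subject = res$per_subject)
}
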