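## age_core module: calibration of the multi-region equilibrium model on the
## balanced SAM and land-cell layer, and the damped-Newton solver for the
## market-clearing system.
##
## Model summary. Each region has one representative activity per sector:
## Leontief in intermediate composites, CES over labor, capital and (for
## land-using sectors) a CES composite of cover-specific land across the
## region's cells. Land within each cell is supplied through the nested
## sum-preserving CET: level 1 splits total cell area between forest, natural
## grassland, other natural cover and agricultural land (the deforestation
## margin, elasticity sigma_nat); level 2 splits agricultural land between
## pasture and cropland (sigma_agpast); level 3 allocates cropland across
## crops (sigma_crop). Non-forest natural covers earn a fixed reservation
## rent; forest rent is set on the forestry market. Trade follows the
## Armington structure (domestic vs import composite, then across origins).
## Households own all factors and spend through a linear expenditure system
## calibrated from income elasticities and a Frisch parameter. Benchmark
## prices are normalised to 1, so the solver works in ratios to benchmark.

#' Calibrate the equilibrium model
#'
#' Reads benchmark value flows off a balanced SAM, imputes benchmark land
#' rents per cell-cover from the land accounts and physical areas, and stores
#' every share and scale coefficient the solver needs. With all benchmark
#' prices at 1, CES/CET share coefficients equal benchmark value shares, and
#' solving the calibrated model with zero shocks reproduces the benchmark.
#'
#' @param sam_obj a `"soy_sam"` (possibly compliance-split).
#' @param config the matching [world_config()].
#' @param elasticities optional override of `config$elasticities`.
#' @return object of class `"soy_model"`.
#' @export
calibrate <- function(sam_obj, config, elasticities = NULL) {
  el <- elasticities %||% config$elasticities
  fl <- extract_flows(sam_obj, config)
  sectors <- config$sectors
  sn <- sectors$sector
  regions <- config$regions
  J <- length(sn); R <- length(regions)
  cells <- sam_obj$cells
  n_c <- nrow(cells)
  cov_of <- cover_of_sector(sectors)
  mk <- marketed_covers(sectors)
  crop_sectors <- sn[sectors$land_cover == "crop"]

  V_out <- fl$V_out
  abort_if(any(V_out <= 0), "calibration requires positive output values")
  aio <- fl$V_int
  for (r in regions) {
    m <- fl$V_int[, , r, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- c(J, J)
    aio[, , r] <- m / rep(V_out[, r], each = J)
  }

  V_landtot <- matrix(0, J, R, dimnames = list(sn, regions))
  omega <- matrix(0, n_c, J, dimnames = list(cells$cell_id, sn))
  for (j in sn) for (r in regions) {
    cid <- cells$cell_id[cells$region == r]
    if (is.na(cov_of[j])) next
    v <- fl$V_land[j, cid, cov_of[j]]
    V_landtot[j, r] <- sum(v)
    if (sum(v) > 0) omega[cid, j] <- v / sum(v)
  }
  VVA <- fl$V_lab + fl$V_cap + V_landtot
  abort_if(any(VVA <= 0), "zero value added in some activity")
  for (j in sn) {
    sig <- el$sigma_va[j]
    bad <- V_landtot[j, ] == 0 & sectors$land_cover[match(j, sn)] != "none"
    abort_if(any(bad) && sig > 0,
             paste0("zero-value land nest with positive elasticity: ", j))
  }
  theta_L <- fl$V_lab / VVA
  theta_K <- fl$V_cap / VVA
  theta_T <- V_landtot / VVA
  avash <- VVA / V_out

  ## Armington structure
  QA0 <- apply(fl$V_src, c(1, 3), sum)
  qd0 <- matrix(0, J, R, dimnames = list(sn, regions))
  for (i in sn) for (s in regions) qd0[i, s] <- fl$V_src[i, s, s]
  qm0 <- QA0 - qd0
  wsrc <- array(0, c(J, R, R), dimnames = list(sn, regions, regions))
  for (i in sn) for (s in regions) {
    if (qm0[i, s] > 0) {
      w <- fl$V_src[i, , s]; w[s] <- 0
      wsrc[i, , s] <- w / sum(w)
    }
  }

  ## LES demand from income elasticities and the Frisch parameter
  Y0 <- colSums(fl$V_hh)
  bshare <- sweep(fl$V_hh, 2, Y0, "/")
  eta <- el$income[sn]
  beta <- sweep(bshare * eta, 2, colSums(bshare * eta), "/")
  Ystar0 <- -Y0 / el$frisch
  Vgam <- fl$V_hh - sweep(beta, 2, Ystar0, "*")

  ## land leaves: physical areas, benchmark rents
  area <- function(col) if (col %in% names(cells)) cells[[col]] else
    rep(0, n_c)
  leaf_area <- cbind(forest = area("area_forest"),
                     grass = area("area_grass"),
                     onat = pmax(area("area_othernat") - area("area_grass"), 0),
                     pasture = area("area_pasture"))
  for (cs in crop_sectors)
    leaf_area <- cbind(leaf_area,
                       stats::setNames(list(area(paste0("area_crop_", cs))),
                                       paste0("crop_", cs))[[1]])
  colnames(leaf_area) <- c("forest", "grass", "onat", "pasture",
                           paste0("crop_", crop_sectors))
  rownames(leaf_area) <- cells$cell_id

  VL0 <- matrix(0, n_c, length(mk), dimnames = list(cells$cell_id, mk))
  if (n_c > 0) for (v in mk) {
    m <- fl$V_land[, , v, drop = FALSE][, , 1, drop = FALSE]
    dim(m) <- c(J, n_c)
    VL0[, v] <- colSums(m)
  }
  rho0 <- VL0 / leaf_area[, mk]
  rho0[!is.finite(rho0)] <- 0
  abort_if(any(VL0 > 0 & leaf_area[, mk] == 0),
           "land payments to a cover with zero physical area")

  ## unknown layout: p (J*R), q (J*R), wL (R), wK (R), rho (marketed leaves)
  lnd <- expand.grid(cell = cells$cell_id, cover = mk,
                     stringsAsFactors = FALSE)
  lnd <- lnd[VL0[cbind(lnd$cell, lnd$cover)] > 0, , drop = FALSE]
  rownames(lnd) <- NULL
  lnd$region <- cells[lnd$cell, "region"]
  lnd$sector <- sn[match(lnd$cover, cov_of)]
  rho_idx <- matrix(0L, n_c, length(mk), dimnames = list(cells$cell_id, mk))
  rho_idx[cbind(lnd$cell, lnd$cover)] <- seq_len(nrow(lnd))

  structure(list(
    config = config, elasticities = el, sectors = sectors, sn = sn,
    regions = regions, J = J, R = R, cells = cells, n_c = n_c,
    cov_of = cov_of, crop_sectors = crop_sectors, mk = mk,
    V_out = V_out, V_int = fl$V_int, aio = aio, avash = avash,
    theta_L = theta_L, theta_K = theta_K, theta_T = theta_T,
    V_lab = fl$V_lab, V_cap = fl$V_cap, V_land = fl$V_land,
    omega = omega, V_landtot = V_landtot,
    QA0 = QA0, qd0 = qd0, qm0 = qm0, wsrc = wsrc,
    beta = beta, Vgam = Vgam, Y0 = Y0,
    endow = fl$endow,
    leaf_area = leaf_area, VL0 = VL0, rho0 = rho0, lnd = lnd,
    rho_idx = rho_idx,
    freeze = NULL
  ), class = "soy_model")
}

#' @export
print.soy_model <- function(x, ...) {
  cat("<soy_model> ", x$J, " sectors x ", x$R, " regions, ", x$n_c,
      " land cells, ", 2 * x$J * x$R + 2 * x$R + nrow(x$lnd),
      " unknowns", if (!is.null(x$freeze)) " [conversion freeze applied]",
      "\n", sep = "")
  invisible(x)
}

#' Default medium-run drivers (benchmark year to benchmark year + 5)
#'
#' Proportional changes over the five-year horizon: regional labor and
#' capital endowment growth (population plus income accumulation), Hicks-
#' neutral agricultural productivity growth, and a biofuel-driven shift in
#' oilseed-processing demand in the biofuel-mandating importers.
#'
#' @param config a [world_config()].
#' @return named list of shock multipliers, class `"soy_shocks"`.
#' @export
default_drivers <- function(config) {
  regions <- config$regions
  roles <- config$roles
  sn <- config$sectors$sector
  lab <- stats::setNames(rep(1.05, length(regions)), regions)
  cap <- stats::setNames(rep(1.12, length(regions)), regions)
  lab[intersect(roles$china, regions)] <- 1.08
  cap[intersect(roles$china, regions)] <- 1.30
  lab[intersect(roles$policy, regions)] <- 1.06
  cap[intersect(roles$policy, regions)] <- 1.16
  lab[intersect(roles$eu, regions)] <- 1.02
  cap[intersect(roles$eu, regions)] <- 1.06
  tfp <- matrix(1, length(sn), length(regions), dimnames = list(sn, regions))
  agr <- config$sectors$land_cover != "none"
  tfp[agr, ] <- 1.04
  bio <- stats::setNames(rep(1, length(regions)), regions)
  bio[intersect(c(roles$spare, roles$eu), regions)] <- 1.25
  ## feed/protein demand growth in the Chinese import market
  bio[intersect(roles$china, regions)] <- 1.40
  structure(list(endow_growth = rbind(LAB = lab, CAP = cap), tfp = tfp,
                 biofuel = bio, numeraire = 1), class = "soy_shocks")
}

zero_shocks <- function(model) {
  structure(list(
    endow_growth = matrix(1, 2, model$R,
                          dimnames = list(c("LAB", "CAP"), model$regions)),
    tfp = matrix(1, model$J, model$R,
                 dimnames = list(model$sn, model$regions)),
    biofuel = stats::setNames(rep(1, model$R), model$regions),
    numeraire = 1), class = "soy_shocks")
}

merge_shocks <- function(model, shocks) {
  z <- zero_shocks(model)
  if (is.null(shocks)) return(z)
  if (!is.null(shocks$endow_growth))
    z$endow_growth[rownames(shocks$endow_growth),
                   colnames(shocks$endow_growth)] <- shocks$endow_growth
  if (!is.null(shocks$tfp)) {
    t <- shocks$tfp
    z$tfp[rownames(t), colnames(t)] <- t
  }
  if (!is.null(shocks$biofuel)) z$biofuel[names(shocks$biofuel)] <-
      shocks$biofuel
  if (!is.null(shocks$numeraire)) z$numeraire <- shocks$numeraire
  z
}

## Nested land supply for one cell. Returns leaf areas (physical) and, for
## frozen cells, the endogenous retention subsidy (in benchmark-rent units).
## `num` is the numeraire index: reservation rents on unmanaged covers are
## real constants and scale with it, preserving homogeneity.
cell_land_supply <- function(model, ci, rho_hat, frozen, definition,
                             num = 1) {
  el <- model$elasticities
  cells <- model$cells
  r <- cells$region[ci]
  la <- model$leaf_area[ci, ]
  crop_cov <- paste0("crop_", model$crop_sectors)
  A <- sum(la)
  gidx <- model$rho_idx[ci, ]
  rhat_of <- function(v) if (gidx[v] > 0) rho_hat[gidx[v]] else num

  r_crop <- vapply(crop_cov, rhat_of, numeric(1))
  ac0 <- la[crop_cov]
  s_crop <- if (sum(ac0) > 0) ac0 / sum(ac0) else ac0
  Rcrop <- cet_revenue_index(r_crop, s_crop, el$sigma_crop[r])
  ap0 <- la["pasture"]; ag0A <- ap0 + sum(ac0)
  Rag <- cet_revenue_index(c(rhat_of("pasture"), Rcrop),
                           c(ap0, sum(ac0)) / ag0A, el$sigma_agpast[r])

  lv1_a0 <- c(forest = unname(la["forest"]), grass = unname(la["grass"]),
              onat = unname(la["onat"]), ag = unname(ag0A))
  lv1_r <- c(forest = rhat_of("forest"), grass = num, onat = num,
             ag = unname(Rag))
  sig_nat <- el$sigma_nat[r]
  subsidy <- NA_real_

  if (!frozen) {
    lv1 <- cet_allocate(A, lv1_a0, lv1_r, sig_nat, method = "additive")
  } else {
    fz <- if (definition == "B") c("forest", "grass") else "forest"
    fz <- fz[lv1_a0[fz] > 0]
    if (length(fz) == 0) {
      lv1 <- cet_allocate(A, lv1_a0, lv1_r, sig_nat, method = "additive")
    } else {
      free <- setdiff(names(lv1_a0), fz)
      rest <- A - sum(lv1_a0[fz])
      lv1 <- lv1_a0
      if (sum(lv1_a0[free]) > 0 && rest > 0) {
        lv1[free] <- cet_allocate(rest, lv1_a0[free], lv1_r[free], sig_nat,
                                  method = "additive")
      }
      ## endogenous retention subsidy: the rent wedge on the frozen covers
      ## that rationalises the frozen share in the unconstrained share form
      if (sig_nat > 0 && sum(lv1_a0[free]) > 0) {
        sF0 <- sum(lv1_a0[fz]) / A
        theta <- sF0                      # area held at its benchmark level
        U <- sum((lv1_a0[free] / A) * lv1_r[free]^sig_nat)
        rF <- sum(lv1_r[fz] * lv1_a0[fz]) / sum(lv1_a0[fz])
        subsidy <- (theta * U / ((1 - theta) * sF0))^(1 / sig_nat) - rF
      } else subsidy <- 0
    }
  }

  ag <- unname(lv1["ag"])
  if (ag0A > 0 && ag > 0) {
    ag_split <- cet_allocate(ag, c(pasture = unname(ap0), crop = sum(ac0)),
                             c(pasture = rhat_of("pasture"),
                               crop = unname(Rcrop)),
                             el$sigma_agpast[r], method = "additive")
  } else ag_split <- c(pasture = 0, crop = 0)
  crops <- if (sum(ac0) > 0 && ag_split["crop"] > 0)
    cet_allocate(unname(ag_split["crop"]), ac0, r_crop, el$sigma_crop[r],
                 method = "additive")
  else stats::setNames(rep(0, length(crop_cov)), crop_cov)

  out <- c(forest = unname(lv1["forest"]), grass = unname(lv1["grass"]),
           onat = unname(lv1["onat"]),
           pasture = unname(ag_split["pasture"]), crops)
  list(areas = out, subsidy = subsidy)
}

## Full excess-demand / zero-profit residual system in benchmark ratios.
model_residual <- function(model, x, shocks, want_state = FALSE) {
  J <- model$J; R <- model$R; sn <- model$sn; regions <- model$regions
  el <- model$elasticities
  n_jr <- J * R
  phat <- matrix(x[seq_len(n_jr)], J, R, dimnames = list(sn, regions))
  qhat <- matrix(x[n_jr + seq_len(n_jr)], J, R, dimnames = list(sn, regions))
  wL <- x[2 * n_jr + seq_len(R)]; names(wL) <- regions
  wK <- x[2 * n_jr + R + seq_len(R)]; names(wK) <- regions
  rho <- x[2 * n_jr + 2 * R + seq_len(nrow(model$lnd))]

  ## Armington price indices
  pm <- matrix(1, J, R, dimnames = list(sn, regions))
  PA <- matrix(1, J, R, dimnames = list(sn, regions))
  for (i in seq_len(J)) {
    s2 <- el$armington2[sn[i]]; s1 <- el$armington1[sn[i]]
    W <- model$wsrc[i, , ]
    has_m <- colSums(W) > 0
    if (any(has_m))
      pm[i, has_m] <- colSums(W[, has_m, drop = FALSE] *
                                phat[i, ]^(1 - s2))^(1 / (1 - s2))
    shd <- model$qd0[i, ] / model$QA0[i, ]
    shm <- 1 - shd
    if (abs(s1 - 1) < 1e-12) {
      PA[i, ] <- phat[i, ]^shd * pm[i, ]^shm
    } else {
      PA[i, ] <- (shd * phat[i, ]^(1 - s1) +
                    shm * pm[i, ]^(1 - s1))^(1 / (1 - s1))
    }
  }

  ## land composite price index per land-using activity
  sigc <- el$sigma_cells
  rho_full <- matrix(1, model$n_c, length(model$mk),
                     dimnames = dimnames(model$rho_idx))
  pos <- model$rho_idx > 0
  rho_full[pos] <- rho[model$rho_idx[pos]]
  Pl <- matrix(1, J, R, dimnames = list(sn, regions))
  for (j in sn) {
    if (is.na(model$cov_of[j])) next
    rv <- rho_full[, model$cov_of[j]]
    for (r in regions) {
      cid <- which(model$cells$region == r)
      w <- model$omega[cid, j]
      if (sum(w) <= 0) next
      Pl[j, r] <- sum(w * rv[cid]^(1 - sigc))^(1 / (1 - sigc))
    }
  }

  ## unit value-added cost and zero profit
  cva <- matrix(1, J, R, dimnames = list(sn, regions))
  for (j in sn) {
    sv <- el$sigma_va[j]
    tL <- model$theta_L[j, ]; tK <- model$theta_K[j, ]; tT <- model$theta_T[j, ]
    if (abs(sv - 1) < 1e-12) {
      cva[j, ] <- wL^tL * wK^tK * ifelse(tT > 0, Pl[j, ]^tT, 1)
    } else {
      cva[j, ] <- (tL * wL^(1 - sv) + tK * wK^(1 - sv) +
                     tT * Pl[j, ]^(1 - sv))^(1 / (1 - sv))
    }
  }
  pva <- cva / shocks$tfp
  R_zp <- matrix(0, J, R)
  for (r in seq_len(R))
    R_zp[, r] <- phat[, r] -
      (crossprod(model$aio[, , r], PA[, r])[, 1] + model$avash[, r] * pva[, r])

  ## land supply per cell (and retention subsidies)
  fzcells <- model$freeze$cells %||% character(0)
  fzdef <- model$freeze$definition %||% "A"
  sup <- matrix(0, model$n_c, ncol(model$leaf_area),
                dimnames = dimnames(model$leaf_area))
  subsidy <- rep(NA_real_, model$n_c)
  for (ci in seq_len(model$n_c)) {
    ls <- cell_land_supply(model, ci, rho,
                           frozen = model$cells$cell_id[ci] %in% fzcells,
                           definition = fzdef, num = shocks$numeraire)
    sup[ci, ] <- ls$areas[colnames(sup)]
    subsidy[ci] <- ls$subsidy
  }

  ## household income: factor endowments plus land rents at supplied areas
  land_val <- rho_full * sup[, model$mk] / model$leaf_area[, model$mk]
  land_val[!is.finite(land_val)] <- 0
  land_val <- land_val * model$VL0
  Y <- wL * model$endow["LAB", ] * shocks$endow_growth["LAB", ] +
    wK * model$endow["CAP", ] * shocks$endow_growth["CAP", ]
  for (r in regions)
    Y[r] <- Y[r] + sum(land_val[model$cells$region == r, ])

  ## LES household demand (quantities at benchmark prices)
  gam <- model$Vgam
  gam[model$crop_sectors[1], ] <- gam[model$crop_sectors[1], ] *
    shocks$biofuel
  sup_num <- Y - colSums(gam * PA)
  x_hh <- gam + sweep(model$beta, 2, sup_num, "*") / PA

  ## composite absorption and sourcing
  QA <- matrix(0, J, R, dimnames = list(sn, regions))
  for (s in seq_len(R)) QA[, s] <- model$V_int[, , s] %*% qhat[, s] +
      x_hh[, s]
  Rmk <- matrix(0, J, R)
  qd <- matrix(0, J, R); qm <- matrix(0, J, R)
  for (i in seq_len(J)) {
    s1 <- el$armington1[sn[i]]
    qd[i, ] <- model$qd0[i, ] * (QA[i, ] / model$QA0[i, ]) *
      (phat[i, ] / PA[i, ])^(-s1)
    qm[i, ] <- model$qm0[i, ] * (QA[i, ] / model$QA0[i, ]) *
      (pm[i, ] / PA[i, ])^(-s1)
  }
  for (i in seq_len(J)) {
    s2 <- el$armington2[sn[i]]
    W <- model$wsrc[i, , ]
    ## exports of origin o: sum_s wsrc[o,s] qm0[s] qmhat[s] (p_o/pm_s)^-s2
    expq <- (phat[i, ]^(-s2)) *
      (W %*% (qm[i, ] * pm[i, ]^(s2)))[, 1]
    Rmk[i, ] <- (qhat[i, ] * model$V_out[i, ] - (qd[i, ] + expq)) /
      model$V_out[i, ]
  }

  ## factor demands
  wLm <- matrix(wL, J, R, byrow = TRUE)
  wKm <- matrix(wK, J, R, byrow = TRUE)
  sv <- el$sigma_va[sn]
  fL <- model$V_lab * qhat * wLm^(-sv) * cva^(sv) / shocks$tfp
  fK <- model$V_cap * qhat * wKm^(-sv) * cva^(sv) / shocks$tfp
  fac_scale <- pmax(model$endow, 1e-9 * sum(model$V_out))  # guard zero factors
  R_lab <- (colSums(fL) - model$endow["LAB", ] *
              shocks$endow_growth["LAB", ]) / fac_scale["LAB", ]
  R_cap <- (colSums(fK) - model$endow["CAP", ] *
              shocks$endow_growth["CAP", ]) / fac_scale["CAP", ]
  ## a factor nobody owns has no market: pin its price instead
  R_lab[model$endow["LAB", ] == 0] <- wL[model$endow["LAB", ] == 0] - 1
  R_cap[model$endow["CAP", ] == 0] <- wK[model$endow["CAP", ] == 0] - 1

  ## land demand per marketed leaf vs supply
  Lcomp <- model$V_landtot * qhat * Pl^(-sv) * cva^(sv) / shocks$tfp
  R_lnd <- numeric(nrow(model$lnd))
  for (k in seq_len(nrow(model$lnd))) {
    cc <- model$lnd$cell[k]; v <- model$lnd$cover[k]
    j <- model$lnd$sector[k]; r <- model$lnd$region[k]
    ci <- match(cc, model$cells$cell_id)
    dem_hat <- (Lcomp[j, r] / model$V_landtot[j, r]) *
      (rho_full[ci, v] / Pl[j, r])^(-sigc)
    R_lnd[k] <- dem_hat - sup[ci, v] / model$leaf_area[ci, v]
  }

  ## numeraire: factor price index of region 1 fixed
  th <- model$endow[, 1] / sum(model$endow[, 1])
  R_num <- th["LAB"] * wL[1] + th["CAP"] * wK[1] - shocks$numeraire

  res <- c(as.numeric(R_zp), as.numeric(Rmk),
           c(R_num, R_lab[-1]), R_cap, R_lnd)
  if (!want_state) return(res)
  list(residual = res, phat = phat, qhat = qhat, wL = wL, wK = wK,
       rho = rho_full, PA = PA, pm = pm, Pl = Pl, cva = cva, Y = Y,
       x_hh = x_hh, QA = QA, sup = sup, subsidy = subsidy,
       walras_excess = R_lab[1] * model$endow["LAB", 1] * wL[1])
}

#' Solve the model for a market-clearing equilibrium
#'
#' Damped Newton iteration on the excess-demand / zero-profit system in
#' levels, with a finite-difference Jacobian and step halving. The numeraire
#' is the primary-factor price index of the first region. Non-convergence or
#' a singular Jacobian raises an error with diagnostics, never a silent bad
#' state.
#'
#' @param model a calibrated `"soy_model"` (optionally with a conversion
#'   freeze from [apply_zdsp()]).
#' @param shocks a `"soy_shocks"` list (see [default_drivers()]); `NULL` for
#'   the zero-shock benchmark replication.
#' @param control list: `tol` (max |residual|, default 1e-9), `max_iter`,
#'   `verbose`.
#' @return object of class `"soy_equilibrium"`.
#' @export
solve_equilibrium <- function(model, shocks = NULL, control = list()) {
  tol <- control$tol %||% 1e-9
  max_iter <- control$max_iter %||% 40L
  verbose <- isTRUE(control$verbose)
  sh <- merge_shocks(model, shocks)
  n <- 2 * model$J * model$R + 2 * model$R + nrow(model$lnd)
  x <- control$x_start %||% rep(1, n)
  Fx <- model_residual(model, x, sh)
  build_jacobian <- function(x, Fx) {
    Jm <- matrix(0, n, n)
    h <- 1e-7
    for (k in seq_len(n)) {
      xk <- x; xk[k] <- xk[k] + h
      Jm[, k] <- (model_residual(model, xk, sh) - Fx) / h
    }
    Jm
  }
  Jm <- NULL
  stale <- 0L
  for (it in seq_len(max_iter)) {
    nrm <- max(abs(Fx))
    if (verbose) message(sprintf("iter %d: max residual %.3e", it - 1, nrm))
    if (nrm < tol) break
    if (is.null(Jm)) {
      Jm <- build_jacobian(x, Fx)
      stale <- 0L
    }
    dx <- tryCatch(solve(Jm, Fx), error = function(e) {
      if (stale > 0) return(NULL)
      stop(paste0("singular Jacobian in equilibrium solve (",
                  conditionMessage(e),
                  "); check the closure/numeraire specification"))
    })
    if (is.null(dx)) { Jm <- NULL; next }  # stale factor broke: rebuild
    t_step <- min(1, 0.8 / max(dx / x, 1e-12))  # keep iterates positive
    repeat {
      x_new <- x - t_step * dx
      F_new <- model_residual(model, x_new, sh)
      if (max(abs(F_new)) < nrm || t_step < 1 / 128) break
      t_step <- t_step / 2
    }
    ## a stale Jacobian that stops making progress gets rebuilt, and the
    ## endgame always runs on a fresh one
    if (stale > 0 && (max(abs(F_new)) > 0.7 * nrm || nrm < 100 * tol)) {
      Jm <- NULL
      next
    }
    if (max(abs(F_new)) >= nrm && stale == 0L) {
      ## fresh Jacobian and still no progress: take the damped step anyway
      x_new <- x - dx / 128
      F_new <- model_residual(model, x_new, sh)
    }
    x <- x_new; Fx <- F_new
    stale <- stale + 1L
  }
  if (max(abs(Fx)) >= tol)
    stop(sprintf(
      "equilibrium solver failed to converge: max residual %.3e after %d iterations",
      max(abs(Fx)), max_iter))
  st <- model_residual(model, x, sh, want_state = TRUE)
  land <- data.frame(cell_id = rep(model$cells$cell_id,
                                   ncol(model$leaf_area)),
                     region = rep(model$cells$region, ncol(model$leaf_area)),
                     cover = rep(colnames(model$leaf_area),
                                 each = model$n_c),
                     area_benchmark = as.numeric(model$leaf_area),
                     area = as.numeric(st$sup),
                     stringsAsFactors = FALSE)
  structure(list(
    phat = st$phat, qhat = st$qhat, wL = st$wL, wK = st$wK, rho = st$rho,
    PA = st$PA, income = st$Y, x_hh = st$x_hh, QA = st$QA,
    land = land, subsidy = stats::setNames(st$subsidy,
                                           model$cells$cell_id),
    residual_max = max(abs(st$residual)),
    walras = abs(st$walras_excess) / sum(model$V_out),
    shocks = sh, freeze = model$freeze,
    converged = max(abs(st$residual)) < tol
  ), class = "soy_equilibrium")
}

#' @export
print.soy_equilibrium <- function(x, ...) {
  cat("<soy_equilibrium> max residual ", format(x$residual_max, digits = 3),
      "; Walras residual ", format(x$walras, digits = 3),
      if (!is.null(x$freeze)) "; conversion freeze active", "\n", sep = "")
  invisible(x)
}

#' Benchmark replication check
#'
#' Solves the calibrated model with zero shocks and reports the residual at
#' the benchmark point: a correctly calibrated model replicates its benchmark
#' exactly (up to solver tolerance).
#'
#' @param model a `"soy_model"`.
#' @param tol residual tolerance for the pass flag.
#' @return list with `max_residual`, `pass`, and the worst equations if any.
#' @export
replication_check <- function(model, tol = 1e-8) {
  sh <- zero_shocks(model)
  n <- 2 * model$J * model$R + 2 * model$R + nrow(model$lnd)
  res <- model_residual(model, rep(1, n), sh)
  worst <- order(abs(res), decreasing = TRUE)[seq_len(min(5, length(res)))]
  list(max_residual = max(abs(res)), pass = max(abs(res)) < tol,
       worst_equations = worst)
}

#' Apply a zero-deforestation conversion freeze
#'
#' Marks the compliant cells: in each, the restricted cover (forest under
#' definition A; forest plus natural grassland under definition B, which
#' inside the Amazon coincides with A) is held at its benchmark area through
#' a constraint swap — the cover area becomes exogenous and the compensating
#' retention subsidy endogenous. Subsidy receipts and payments net out within
#' the regional household, so only the allocation margin is affected.
#'
#' @param model a `"soy_model"`.
#' @param cells_under_policy character vector of compliant cell ids.
#' @param forest_definition `"A"` or `"B"`.
#' @return the model with the freeze attached.
#' @export
apply_zdsp <- function(model, cells_under_policy, forest_definition = "A") {
  missing <- setdiff(cells_under_policy, model$cells$cell_id)
  abort_if(length(missing) > 0,
           paste("covered cells absent from model:",
                 paste(missing, collapse = ", ")))
  model$freeze <- list(cells = cells_under_policy,
                       definition = match.arg(forest_definition, c("A", "B")))
  model
}

#' Run the no-restriction baseline
#'
#' Solves the model under the medium-run drivers with no land restriction
#' anywhere (the ASM is deliberately excluded from the baseline so its impact
#' can be reported against it).
#'
#' @param model a `"soy_model"`.
#' @param drivers a `"soy_shocks"` list; defaults to [default_drivers()].
#' @param control solver control list.
#' @return a `"soy_equilibrium"`.
#' @export
run_baseline <- function(model, drivers = NULL, control = list()) {
  model$freeze <- NULL
  if (is.null(drivers)) drivers <- default_drivers(model$config)
  solve_equilibrium(model, drivers, control)
}

#' Run a policy counterfactual
#'
#' Same drivers as the baseline, with the conversion freeze of the scenario
#' footprint applied.
#'
#' @param model a `"soy_model"`.
#' @param drivers a `"soy_shocks"` list (must match the baseline's).
#' @param cells_under_policy compliant cell ids.
#' @param forest_definition `"A"` or `"B"`.
#' @param control solver control list.
#' @return a `"soy_equilibrium"`.
#' @export
run_counterfactual <- function(model, drivers = NULL, cells_under_policy,
                               forest_definition = "A", control = list()) {
  if (is.null(drivers)) drivers <- default_drivers(model$config)
  model <- apply_zdsp(model, cells_under_policy, forest_definition)
  solve_equilibrium(model, drivers, control)
}
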