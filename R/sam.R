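## Social accounting matrix: raw structured flows -> RAS-balanced SAM ->
## calibration flow arrays. Accounts: activities ACT.<sector>.<region>,
## factors LAB.<region> / CAP.<region>, land LND.<cell>.<cover>, households
## HH.<region>. Row = receipts, column = outlays; a balanced SAM has equal
## row and column sums per account, which delivers every accounting identity
## the equilibrium calibration relies on (zero profit, budget balance,
## market clearing in benchmark values).

sam_account_table <- function(config, cells) {
  sectors <- config$sectors$sector
  regions <- config$regions
  mk <- marketed_covers(config$sectors)
  acts <- expand.grid(sector = sectors, region = regions,
                      stringsAsFactors = FALSE)
  lnd <- expand.grid(cell = cells$cell_id, cover = mk,
                     stringsAsFactors = FALSE)
  lnd$region <- if (nrow(lnd)) cells[lnd$cell, "region"] else character(0)
  lnd_acc <- if (nrow(lnd)) paste("LND", lnd$cell, lnd$cover, sep = ".")
             else character(0)
  data.frame(
    account = c(paste("ACT", acts$sector, acts$region, sep = "."),
                paste("LAB", regions, sep = "."),
                paste("CAP", regions, sep = "."),
                lnd_acc,
                paste("HH", regions, sep = ".")),
    type = c(rep("ACT", nrow(acts)), rep("LAB", length(regions)),
             rep("CAP", length(regions)), rep("LND", nrow(lnd)),
             rep("HH", length(regions))),
    sector = c(acts$sector, rep(NA, 2 * length(regions)),
               rep(NA, nrow(lnd)), rep(NA, length(regions))),
    region = c(acts$region, regions, regions, lnd$region, regions),
    cell = c(rep(NA, nrow(acts) + 2 * length(regions)), lnd$cell,
             rep(NA, length(regions))),
    cover = c(rep(NA, nrow(acts) + 2 * length(regions)), lnd$cover,
              rep(NA, length(regions))),
    stringsAsFactors = FALSE
  )
}

## structural cost/demand priors used to lay out the raw SAM
sam_priors <- function(sectors) {
  sn <- sectors$sector
  lc <- sectors$land_cover
  int_share <- stats::setNames(ifelse(lc == "crop", 0.35,
                        ifelse(lc == "pasture", 0.45,
                        ifelse(lc == "forest", 0.30,
                        ifelse(sn %in% c("pfd", "ofd", "plv", "vol"), 0.60,
                               0.45)))), sn)
  land_of_va <- stats::setNames(ifelse(lc == "crop", 0.25,
                        ifelse(lc == "pasture", 0.35,
                        ifelse(lc == "forest", 0.50, 0))), sn)
  ## input mix: column j = composition of sector j's intermediate purchases
  mix <- matrix(0.02, length(sn), length(sn), dimnames = list(sn, sn))
  mfs_like <- sn[lc == "none" & !(sn %in% c("pfd", "ofd", "plv", "vol"))]
  food_like <- sn[sn %in% c("pfd", "ofd", "plv", "vol")]
  if (length(mfs_like) == 0) mfs_like <- sn[length(sn)]
  for (j in sn) {
    if (lc[match(j, sn)] %in% c("crop", "forest")) {
      mix[mfs_like, j] <- 0.8 / length(mfs_like)
    } else if (lc[match(j, sn)] == "pasture") {
      mix[sn[lc == "crop"], j] <- 0.5 / sum(lc == "crop")  # feed
      mix[mfs_like, j] <- 0.4 / length(mfs_like)
    } else if (j %in% food_like) {
      mix[sn[lc == "crop"], j] <- 0.45 / sum(lc == "crop") # crush/processing
      mix[sn[lc == "pasture"], j] <- 0.15
      mix[mfs_like, j] <- 0.3 / length(mfs_like)
    } else {
      mix[mfs_like, j] <- 0.75 / length(mfs_like)
      if (length(food_like)) mix[food_like, j] <- 0.08 / length(food_like)
    }
    mix[, j] <- mix[, j] / sum(mix[, j])
  }
  hh <- stats::setNames(ifelse(lc == "crop", 0.03,
               ifelse(lc == "pasture", 0.05,
               ifelse(lc == "forest", 0.03,
               ifelse(sn %in% food_like, 0.25, 0.55)))), sn)
  hh <- hh / sum(hh)
  list(int_share = int_share, land_of_va = land_of_va, mix = mix,
       hh_share = hh)
}

## baseline output shares of each sector by region role
sam_output_shares <- function(config) {
  sn <- config$sectors$sector
  lc <- config$sectors$land_cover
  regions <- config$regions
  roles <- config$roles
  sh <- matrix(0.01, length(sn), length(regions), dimnames = list(sn, regions))
  ag <- function(osd, gro, lvs, frs) {
    v <- stats::setNames(rep(0.01, length(sn)), sn)
    cs <- sn[lc == "crop"]
    v[cs[1]] <- osd
    if (length(cs) > 1) v[cs[-1]] <- gro / (length(cs) - 1)
    v[lc == "pasture"] <- lvs
    v[lc == "forest"] <- frs
    food <- sn %in% c("pfd", "ofd", "plv", "vol")
    v[food] <- 0.14 / max(sum(food), 1)
    rest <- !(lc != "none") & !food
    v[rest] <- (1 - sum(v[lc != "none"]) - sum(v[food])) / sum(rest)
    v
  }
  for (r in regions) {
    sh[, r] <-
      if (r %in% roles$policy) ag(0.08, 0.05, 0.07, 0.03)
      else if (r %in% roles$frontier) ag(0.12, 0.06, 0.08, 0.04)
      else if (r %in% roles$spare) ag(0.06, 0.06, 0.04, 0.02)
      else if (r %in% roles$eu) ag(0.012, 0.03, 0.03, 0.02)
      else ag(0.02, 0.05, 0.04, 0.02)
  }
  sh
}

## export fractions of output and destination affinities; the soy (first crop)
## affinities carry the destination-segmentation structure
sam_trade_structure <- function(config) {
  sn <- config$sectors$sector
  lc <- config$sectors$land_cover
  regions <- config$regions
  roles <- config$roles
  soy <- sn[lc == "crop"][1]
  exp_frac <- matrix(0.10, length(sn), length(regions),
                     dimnames = list(sn, regions))
  ## grazing livestock is essentially non-traded internationally
  exp_frac[lc == "pasture", ] <- 0.02
  exp_frac[soy, ] <- 0.06
  exp_frac[soy, intersect(roles$policy, regions)] <- 0.55
  exp_frac[soy, intersect(roles$frontier, regions)] <- 0.65
  exp_frac[soy, intersect(roles$spare, regions)] <- 0.35
  aff <- array(0, c(length(sn), length(regions), length(regions)),
               dimnames = list(sn, regions, regions))
  scale <- config$region_scale
  for (i in sn) for (o in regions) {
    w <- scale[setdiff(regions, o)]
    aff[i, o, setdiff(regions, o)] <- w / sum(w)
  }
  seg_target <- function(o) {
    w <- stats::setNames(rep(0.02, length(regions)), regions)
    w[o] <- 0
    if (o %in% roles$policy) { w[roles$china] <- 0.72; w[roles$eu] <- 0.20 }
    else if (o %in% roles$frontier) { w[roles$eu] <- 0.78
                                      w[roles$china] <- 0.10 }
    else if (o %in% roles$spare) { w[roles$china] <- 0.68
                                   w[roles$eu] <- 0.22 }
    else { w[regions] <- scale[regions]; w[o] <- 0 }
    w / sum(w)
  }
  for (o in regions) {
    w <- seg_target(o)
    aff[soy, o, ] <- sharpen_weights(w, config$destination_segmentation)
  }
  list(exp_frac = exp_frac, aff = aff)
}

#' Generate a balanced synthetic social accounting matrix
#'
#' Lays out structured raw value flows (sectoral output by region, input-output
#' cost structure, household demand, bilateral trade with destination
#' segmentation for soy, land rents by biome-AEZ cell imputed proportional to
#' area times a biome productivity factor) and balances them with RAS so every
#' account's receipts equal its outlays to within `tol`.
#'
#' @param config a [world_config()].
#' @param munis municipality table; used to build the policy country's land
#'   cells and rent weights.
#' @param tol relative balance tolerance.
#' @return list of class `"soy_sam"`: `sam` (matrix), `accounts` (metadata),
#'   `cells` (cell table), `sector_weights`.
#' @export
generate_sam <- function(config, munis, tol = 1e-12) {
  abort_if(!inherits(config, "world_config"), "config must be a world_config",
           "soyshift_config_error")
  cl <- aggregate_cells(munis, config)
  build_sam_for_cells(config, cl$cells, cl$sector_weights, tol = tol)
}

## SAM assembly for a given cell layer (reused after compliance splitting)
build_sam_for_cells <- function(config, cells, sector_weights, tol = 1e-12) {
  sectors <- config$sectors
  sn <- sectors$sector
  regions <- config$regions
  J <- length(sn); R <- length(regions)
  pri <- sam_priors(sectors)
  trd <- sam_trade_structure(config)
  cov_of <- cover_of_sector(sectors)

  with_seed(config$seed + 3L, {
    sh <- sam_output_shares(config)
    sh <- sh * matrix(exp(stats::rnorm(J * R, 0, 0.08)), J, R)
    sh <- sweep(sh, 2, colSums(sh), "/")
    V_out <- sweep(sh, 2, config$region_scale[regions] * 1000, "*")
    dimnames(V_out) <- list(sn, regions)

    ## bilateral trade flows per commodity
    V_src <- array(0, c(J, R, R), dimnames = list(sn, regions, regions))
    for (i in sn) for (o in regions) {
      ex <- V_out[i, o] * trd$exp_frac[i, o] * stats::runif(1, 0.9, 1.1)
      dsh <- trd$aff[i, o, ]
      V_src[i, o, ] <- ex * dsh
      V_src[i, o, o] <- V_out[i, o] - ex
    }
    QA0 <- apply(V_src, c(1, 3), sum)

    ## user demands per destination, scaled to absorption
    VA <- V_out * (1 - pri$int_share[sn])
    income <- colSums(VA)
    D_int <- array(0, c(J, J, R), dimnames = list(sn, sn, regions))
    D_hh <- matrix(0, J, R, dimnames = list(sn, regions))
    for (d in regions) {
      for (i in sn) {
        w_int <- V_out[, d] * pri$int_share[sn] * pri$mix[i, ]
        w_hh <- pri$hh_share[i] * income[d]
        tot <- sum(w_int) + w_hh
        D_int[i, , d] <- QA0[i, d] * w_int / tot
        D_hh[i, d] <- QA0[i, d] * w_hh / tot
      }
    }

    ## factor payments; land rents by cell proportional to
    ## area-times-productivity weights
    V_land <- matrix(0, J, R, dimnames = list(sn, regions))
    for (j in sn) V_land[j, ] <- VA[j, ] * pri$land_of_va[j]
    V_lab <- (VA - V_land) * 0.55
    V_cap <- (VA - V_land) * 0.45

    acc <- sam_account_table(config, cells)
    n <- nrow(acc)
    sam <- matrix(0, n, n, dimnames = list(acc$account, acc$account))
    ai <- function(j, r) paste("ACT", j, r, sep = ".")

    for (d in regions) {
      for (j in sn) {
        col <- ai(j, d)
        for (i in sn) {
          if (D_int[i, j, d] <= 0) next
          src <- V_src[i, , d]
          if (sum(src) <= 0) next
          sam[paste("ACT", i, regions, sep = "."), col] <-
            sam[paste("ACT", i, regions, sep = "."), col] +
            D_int[i, j, d] * src / sum(src)
        }
        sam[paste0("LAB.", d), col] <- V_lab[j, d]
        sam[paste0("CAP.", d), col] <- V_cap[j, d]
        if (V_land[j, d] > 0) {
          cid <- cells$cell_id[cells$region == d]
          w <- sector_weights[cid, j]
          sam[paste("LND", cid, cov_of[j], sep = "."), col] <-
            V_land[j, d] * w / sum(w)
        }
      }
      hcol <- paste0("HH.", d)
      for (i in sn) {
        src <- V_src[i, , d]
        if (D_hh[i, d] <= 0 || sum(src) <= 0) next
        sam[paste("ACT", i, regions, sep = "."), hcol] <-
          sam[paste("ACT", i, regions, sep = "."), hcol] +
          D_hh[i, d] * src / sum(src)
      }
      ## factor incomes accrue to the regional household
      sam[paste0("HH.", d), paste0("LAB.", d)] <- sum(V_lab[, d])
      sam[paste0("HH.", d), paste0("CAP.", d)] <- sum(V_cap[, d])
      cid <- cells$cell_id[cells$region == d]
      for (cc in cid) for (v in marketed_covers(sectors)) {
        lr <- paste("LND", cc, v, sep = ".")
        sam[paste0("HH.", d), lr] <- sum(sam[lr, ])
      }
    }

    targets <- (rowSums(sam) + colSums(sam)) / 2
    ## consistency: a household's receipts come only through its region's
    ## single-entry factor columns, so its target must equal their sum
    for (d in regions) {
      fac <- acc$account[acc$type %in% c("LAB", "CAP", "LND") &
                           acc$region == d]
      targets[paste0("HH.", d)] <- sum(targets[fac])
    }
    bal <- balance_matrix(sam, targets, targets, tol = tol, max_iter = 5000L)
    structure(list(sam = bal, accounts = acc, cells = cells,
                   sector_weights = sector_weights),
              class = "soy_sam")
  })
}

#' Check SAM balance
#' @param sam a `"soy_sam"` or plain matrix.
#' @return max |rowsum - colsum| / grand total.
#' @export
sam_imbalance <- function(sam) {
  m <- if (inherits(sam, "soy_sam")) sam$sam else sam
  max(abs(rowSums(m) - colSums(m))) / sum(m)
}

#' Extract calibration flow arrays from a balanced SAM
#'
#' Reads off the benchmark value flows the equilibrium calibration needs:
#' output values, intermediate use, bilateral sourcing, household demand,
#' factor and land payments, endowments. With benchmark prices normalised to
#' one, values equal quantities.
#'
#' @param sam_obj a `"soy_sam"`.
#' @param config the matching [world_config()].
#' @return list of named arrays.
#' @export
extract_flows <- function(sam_obj, config) {
  m <- sam_obj$sam
  acc <- sam_obj$accounts
  cells <- sam_obj$cells
  sn <- config$sectors$sector
  regions <- config$regions
  J <- length(sn); R <- length(regions)
  ai <- function(j, r) paste("ACT", j, r, sep = ".")

  V_out <- matrix(0, J, R, dimnames = list(sn, regions))
  for (j in sn) for (r in regions) V_out[j, r] <- sum(m[ai(j, r), ])

  acts <- acc$account[acc$type == "ACT"]
  hh <- paste0("HH.", regions)
  V_src <- array(0, c(J, R, R), dimnames = list(sn, regions, regions))
  V_int <- array(0, c(J, J, R), dimnames = list(sn, sn, regions))
  V_hh <- matrix(0, J, R, dimnames = list(sn, regions))
  for (i in sn) for (o in regions) {
    row <- ai(i, o)
    for (d in regions) {
      users <- c(ai(sn, d), paste0("HH.", d))
      V_src[i, o, d] <- sum(m[row, users])
      V_int[i, , d] <- V_int[i, , d] + m[row, ai(sn, d)]
      V_hh[i, d] <- V_hh[i, d] + m[row, paste0("HH.", d)]
    }
  }
  ## V_int accumulated origin by origin: fix double counting across origins
  V_int[] <- 0
  for (d in regions) for (j in sn) {
    col <- ai(j, d)
    for (i in sn) V_int[i, j, d] <- sum(m[ai(i, regions), col])
  }

  V_lab <- matrix(0, J, R, dimnames = list(sn, regions))
  V_cap <- matrix(0, J, R, dimnames = list(sn, regions))
  for (j in sn) for (r in regions) {
    V_lab[j, r] <- m[paste0("LAB.", r), ai(j, r)]
    V_cap[j, r] <- m[paste0("CAP.", r), ai(j, r)]
  }
  mk <- marketed_covers(config$sectors)
  V_land <- array(0, c(J, nrow(cells), length(mk)),
                  dimnames = list(sn, cells$cell_id, mk))
  for (j in sn) for (r in regions) {
    cid <- cells$cell_id[cells$region == r]
    for (cc in cid) for (v in mk)
      V_land[j, cc, v] <- m[paste("LND", cc, v, sep = "."), ai(j, r)]
  }
  endow <- rbind(LAB = colSums(V_lab), CAP = colSums(V_cap))
  colnames(endow) <- regions
  list(V_out = V_out, V_src = V_src, V_int = V_int, V_hh = V_hh,
       V_lab = V_lab, V_cap = V_cap, V_land = V_land, endow = endow)
}

#' Generate a complete synthetic mini-world
#'
#' Runs all generators under the config's seed: municipalities, company
#' roster, trader exports, land cells and the balanced SAM.
#'
#' @param config a [world_config()].
#' @return object of class `"soy_world"`.
#' @export
generate_world <- function(config = world_config()) {
  munis <- generate_municipalities(config)
  companies <- generate_companies(config)
  exports <- generate_trader_exports(munis, config, companies)
  sam <- generate_sam(config, munis)
  structure(list(config = config, municipalities = munis,
                 companies = companies, trader_exports = exports,
                 sam = sam),
            class = "soy_world")
}

#' @export
print.soy_world <- function(x, ...) {
  cat("<soy_world> ", length(x$config$regions), " regions x ",
      nrow(x$config$sectors), " sectors; ", nrow(x$municipalities),
      " municipalities; ", nrow(x$sam$cells), " land cells; SAM imbalance ",
      format(sam_imbalance(x$sam), digits = 3), "\n", sep = "")
  invisible(x)
}
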