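# Core lattice engine. State is a plain environment of parallel per-site
# vectors (at most one cell per site, so cell attributes are site-indexed);
# T-cells and vessels are separate compact vectors/tibbles. All user-facing
# summaries are tibbles.

# Moore-neighborhood index matrix: n x 8, column-major site indices with the
# sentinel n+1 for off-grid slots. Per-site vectors are padded with one extra
# element before lookup.
moore_matrix <- function(nx, ny) {
  n <- nx * ny
  xs <- rep.int(seq_len(nx), ny)
  ys <- rep(seq_len(ny), each = nx)
  offs <- cbind(c(-1, 0, 1, -1, 1, -1, 0, 1),
                c(-1, -1, -1, 0, 0, 1, 1, 1))
  NB <- matrix(n + 1L, n, 8L)
  for (k in 1:8) {
    x2 <- xs + offs[k, 1]; y2 <- ys + offs[k, 2]
    ok <- x2 >= 1L & x2 <= nx & y2 >= 1L & y2 <= ny
    NB[ok, k] <- x2[ok] + (y2[ok] - 1L) * nx
  }
  NB
}

# Row-wise max over the 8 neighbor columns of padded per-site values.
row_max_nb <- function(values_padded, nbm) {
  m <- nrow(nbm)
  out <- rep(-Inf, m)
  for (k in 1:8) out <- pmax(out, values_padded[nbm[, k]])
  out
}

# Random choice of one TRUE column per row (uniform among valid), -1 if none.
pick_random_col <- function(valid) {
  m <- nrow(valid)
  scores <- matrix(stats::runif(m * 8L), m, 8L)
  scores[!valid] <- -1
  pick <- max.col(scores, ties.method = "first")
  pick[rowSums(valid) == 0L] <- -1L
  pick
}

new_state <- function(cfg) {
  nx <- cfg$grid_width; ny <- cfg$grid_height; n <- nx * ny
  st <- new.env(parent = emptyenv())
  st$nx <- nx; st$ny <- ny; st$n <- n
  st$NB <- moore_matrix(nx, ny)
  st$kind <- integer(n)                 # 0 empty, 1 tumor, 2 normal, 3 necrotic
  st$pG <- rep(1, n)
  st$pHthr <- rep(cfg$p_H_norm, n)
  st$pP <- rep(cfg$p_P_norm, n)
  st$bound <- numeric(n)
  st$pPeff <- st$pP
  st$Dt <- rep(cfg$tau_min, n)
  st$quies <- logical(n)
  st$clone <- integer(n)
  st$clone_parent <- integer(0)
  st$Tlast <- rep(-Inf, n)
  st$O <- matrix(cfg$O_0, nx, ny)
  st$G <- matrix(cfg$G_0, nx, ny)
  st$Hp <- matrix(protons_of(cfg$pH_0), nx, ny)
  st$A <- matrix(0, nx, ny)
  st$fO <- numeric(n); st$fG <- numeric(n); st$fA <- numeric(n)
  st$pR <- numeric(n); st$ratio <- numeric(n)
  st$vessels <- tibble::tibble(site = integer(), x = integer(), y = integer(),
                               age = numeric(), lifetime = numeric())
  st$tc_site <- integer(0); st$tc_state <- integer(0)
  st$tc_timer <- numeric(0); st$tc_target <- integer(0)
  st$tc_age <- numeric(0)
  st$deferred <- 0L
  st$t <- 0
  st$n_kills <- 0L
  st$kill_log <- list()
  st
}

# Sites of a centered disc holding exactly `n_cells` sites, ordered by radius
# (ties broken by angle); deterministic.
disc_sites <- function(nx, ny, n_cells) {
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  xs <- rep.int(seq_len(nx), ny)
  ys <- rep(seq_len(ny), each = nx)
  r <- sqrt((xs - cx)^2 + (ys - cy)^2)
  ang <- atan2(ys - cy, xs - cx)
  ord <- order(r, ang)
  if (n_cells > nx * ny) stop("geometry cannot host the requested cell count")
  ord[seq_len(n_cells)]
}

new_clones <- function(st, parents_clone, changed) {
  m <- length(parents_clone)
  out <- parents_clone
  idx <- which(changed)
  if (length(idx)) {
    base <- length(st$clone_parent)
    ids <- base + seq_along(idx)
    st$clone_parent <- c(st$clone_parent, parents_clone[idx])
    out[idx] <- ids
  }
  out
}

#' Build the default initial state
#'
#' Normal cells fill every non-vessel site; a disc of `init_tumor_radius`
#' sites of metabolically normal tumor cells (`p_G = 1`, `p_H = p_H_norm`,
#' `p_P = p_P_norm`) sits at the center, each seed its own clone. Division
#' timers start uniformly spread over the cycle.
#'
#' @param cfg An [sim_config()].
#' @param tumor Optional tibble overriding the default disc: columns `site`,
#'   `p_G`, `p_H`, `p_P` (as produced by [make_fig1_fixture()]).
#' @return An internal state environment (consumed by [run_simulation()]).
#' @keywords internal
initial_state <- function(cfg, tumor = NULL) {
  st <- new_state(cfg)
  st$vessels <- initialize_vessels(cfg)
  st$kind[] <- 2L
  st$kind[st$vessels$site] <- 0L
  if (is.null(tumor)) {
    sites <- disc_sites(st$nx, st$ny, ceiling(pi * cfg$init_tumor_radius^2))
    tumor <- tibble::tibble(site = sites, p_G = 1, p_H = cfg$p_H_norm,
                            p_P = cfg$p_P_norm)
  }
  k <- nrow(tumor)
  st$kind[tumor$site] <- 1L
  st$pG[tumor$site] <- tumor$p_G
  st$pHthr[tumor$site] <- tumor$p_H
  st$pP[tumor$site] <- tumor$p_P
  st$pPeff[tumor$site] <- tumor$p_P
  st$Dt[tumor$site] <- stats::runif(k) * cfg$tau_min
  st$clone[tumor$site] <- seq_len(k)
  st$clone_parent <- integer(k)           # seeds are roots
  st
}

#' Mixed / shell initial tumor configurations
#'
#' Builds a circular tumor of `n_low + n_high` cells with an identical
#' phenotype multiset in both modes. `"mixed"`: high-glycolysis cells are
#' uniformly interleaved through the disc (deterministic radial striping).
#' `"shell"`: the `n_high` outermost disc sites carry the high phenotype, so
#' every aggressive cell sits on the rim with at least one non-tumor Moore
#' neighbor.
#'
#' @param cfg An [sim_config()] (provides the lattice shape and normal
#'   phenotype values).
#' @param mode `"mixed"` or `"shell"`.
#' @param n_low,n_high Number of low- and high-glycolysis cells.
#' @param p_G_low,p_G_high Their glycolytic phenotypes. The default aggressive
#'   phenotype (`p_G = 3`) is calibrated so that a contiguous rim acidifies
#'   lethally for surrounding normal tissue but not for itself, while the same
#'   cells interleaved through the disc leave the collective plume subcritical.
#' @param p_H_low,p_H_high Acid-resistance thresholds of the two groups; the
#'   aggressive group defaults to fully acid-adapted (`p_H_min`), the evolved
#'   state that accompanies high glycolysis in this model family.
#' @return A tibble `(site, x, y, p_G, p_H, p_P)` usable as the `tumor`
#'   argument of [run_simulation()].
#' @export
make_fig1_fixture <- function(cfg, mode = c("mixed", "shell"),
                              n_low = 120, n_high = 24,
                              p_G_low = 1, p_G_high = 3,
                              p_H_low = NULL, p_H_high = NULL) {
  mode <- match.arg(mode)
  if (is.null(p_H_low)) p_H_low <- cfg$p_H_norm
  if (is.null(p_H_high)) p_H_high <- cfg$p_H_min
  nx <- cfg$grid_width; ny <- cfg$grid_height
  N <- n_low + n_high
  sites <- disc_sites(nx, ny, N)          # ordered inside-out
  pg <- rep(p_G_low, N)
  ph <- rep(p_H_low, N)
  if (n_high > 0) {
    hi_idx <- if (mode == "shell") {
      seq(N - n_high + 1L, N)             # outermost ring
    } else {
      unique(round(seq(1, N, length.out = n_high)))
    }
    if (length(hi_idx) != n_high) {       # guard against rounding collisions
      hi_idx <- round(seq(1, N, length.out = n_high + 2))[2:(n_high + 1)]
    }
    pg[hi_idx] <- p_G_high
    ph[hi_idx] <- p_H_high
  }
  tibble::tibble(site = sites,
                 x = ((sites - 1L) %% nx) + 1L,
                 y = ((sites - 1L) %/% nx) + 1L,
                 p_G = pg, p_H = ph, p_P = cfg$p_P_norm)
}

solve_state_fields <- function(st, cfg, params, tracking = FALSE) {
  live <- st$kind == 1L | st$kind == 2L
  vs <- st$vessels$site
  settings <- cfg$solver
  if (tracking) settings$max_iterations <- settings$tracking_sweeps
  o <- solve_field(st$O, cfg$D_O, cfg$dx, vs, cfg$O_0,
                   vmax = cfg$V_O * live, km = cfg$k_O, settings = settings,
                   strict = !tracking)
  st$O <- o$field
  Ov <- as.vector(st$O)
  st$fO <- cfg$V_O * Ov / (Ov + cfg$k_O) * live
  demand <- pmax(0, st$pG * params$A_0 - params$ox_yield * st$fO) / 2 * live
  g <- solve_field(st$G, cfg$D_g, cfg$dx, vs, cfg$G_0,
                   vmax = demand, km = cfg$k_G, settings = settings,
                   strict = !tracking)
  st$G <- g$field
  Gv <- as.vector(st$G)
  st$fG <- demand * Gv / (Gv + cfg$k_G)
  st$fA <- 2 * st$fG + params$ox_yield * st$fO
  st$ratio <- st$fA / params$A_0
  B <- buffer_level(cfg$treatment, st$t)
  st$pR <- proton_source_rate(cfg$k_H * st$fG, B)
  H0 <- protons_of(cfg$pH_0)
  lam <- proton_clearance_field(vs, cfg)
  h <- solve_field(st$Hp, cfg$D_H, cfg$dx, vs, H0,
                   decay = lam,
                   source = st$pR * cfg$proton_yield + lam * H0,
                   settings = settings, strict = !tracking)
  st$Hp <- h$field
  st$A <- step_antipdl1_field(st$A, vs, antipdl1_active(cfg$treatment, st$t),
                              cfg, cfg$dt)
  invisible(st)
}

advance_step <- function(st, cfg, params, step_i = 1L) {
  dt <- cfg$dt
  n <- st$n
  if ((step_i - 1L) %% cfg$field_solve_every == 0L) {
    solve_state_fields(st, cfg, params, tracking = TRUE)
  } else {
    # carry the quasi-steady fields; still apply the buffer level and drug
    # schedule, which change discontinuously at window edges
    B <- buffer_level(cfg$treatment, st$t)
    st$pR <- proton_source_rate(cfg$k_H * st$fG, B)
    st$A <- step_antipdl1_field(st$A, st$vessels$site,
                                antipdl1_active(cfg$treatment, st$t), cfg, dt)
  }
  pH_site <- -log10(as.vector(st$Hp))

  ## --- cell fate ---------------------------------------------------------
  li <- which(st$kind == 1L | st$kind == 2L)
  if (length(li)) {
    fate <- update_fate(st$ratio[li], pH_site[li], st$pHthr[li],
                        st$kind[li] == 2L, dt, cfg)
    poor <- st$ratio[li] < cfg$A_d | pH_site[li] < st$pHthr[li]
    dy <- fate == "die"
    if (any(dy)) {
      ds <- li[dy]
      # tumor metabolic/acid death leaves necrotic debris; normal tissue is
      # resorbed (baseline turnover and acid lysis both free the site)
      to_necrotic <- poor[dy] & st$kind[ds] == 1L
      st$kind[ds[to_necrotic]] <- 3L
      st$kind[ds[!to_necrotic]] <- 0L
      st$clone[ds] <- 0L
    }
    st$quies[li] <- fate == "quiescent"
  }

  ## --- cycle progression and division ------------------------------------
  pro <- which(st$kind == 1L & !st$quies &
                 st$ratio >= cfg$A_q)
  if (length(pro)) {
    # tau_min is the minimum cycle time: ATP above baseline cannot shorten
    # the cycle further
    st$Dt[pro] <- st$Dt[pro] - dt * pmin(st$ratio[pro], 1)
    dv <- pro[st$Dt[pro] <= 0]
    if (length(dv)) {
      tc_occ <- logical(n + 1L)
      tc_occ[st$tc_site] <- TRUE
      kindpad <- c(st$kind, 9L)
      nbm <- st$NB[dv, , drop = FALSE]
      valid <- matrix(kindpad[nbm] == 0L & !tc_occ[nbm], nrow = length(dv))
      pick <- pick_random_col(valid)
      perm <- sample.int(length(dv))
      ok <- logical(length(dv))
      dest <- integer(length(dv))
      dest[pick > 0] <- nbm[cbind(which(pick > 0), pick[pick > 0])]
      okp <- pick[perm] > 0 & !duplicated(dest[perm]) & dest[perm] > 0
      ok[perm] <- okp
      st$Dt[dv] <- 0                      # stalled cells wait at the gate
      win <- dv[ok]
      if (length(win)) {
        d2 <- dest[ok]
        ph <- inherit_phenotypes(st$pG[win], st$pHthr[win], st$pP[win], cfg)
        changed <- ph$p_G != st$pG[win] | ph$p_H != st$pHthr[win] |
          ph$p_P != st$pP[win]
        st$kind[d2] <- 1L
        st$pG[d2] <- ph$p_G; st$pHthr[d2] <- ph$p_H; st$pP[d2] <- ph$p_P
        st$bound[d2] <- 0; st$pPeff[d2] <- ph$p_P
        st$quies[d2] <- FALSE
        st$clone[d2] <- new_clones(st, st$clone[win], changed)
        st$Dt[win] <- cfg$tau_min
        st$Dt[d2] <- cfg$tau_min
      }
    }
  }

  ## --- normal tissue homeostasis ------------------------------------------
  # normal cells slowly re-fill vacated sites, balancing baseline turnover;
  # they cannot keep up with acid-cleared zones (re-entrants die at p_delta)
  if (cfg$normal_regrowth > 0) {
    nrm <- which(st$kind == 2L)
    if (length(nrm)) {
      att <- nrm[stats::runif(length(nrm)) < cfg$normal_regrowth * dt]
      if (length(att)) {
        tc_occ2 <- logical(n + 1L)
        tc_occ2[st$tc_site] <- TRUE
        kindpad2 <- c(st$kind, 9L)
        nbm <- st$NB[att, , drop = FALSE]
        valid <- matrix(kindpad2[nbm] == 0L & !tc_occ2[nbm],
                        nrow = length(att))
        pick <- pick_random_col(valid)
        dest <- integer(length(att))
        dest[pick > 0] <- nbm[cbind(which(pick > 0), pick[pick > 0])]
        perm <- sample.int(length(att))
        ok <- logical(length(att))
        ok[perm] <- pick[perm] > 0 & !duplicated(dest[perm]) & dest[perm] > 0
        if (any(ok)) {
          d2 <- dest[ok]
          st$kind[d2] <- 2L
          st$pG[d2] <- 1; st$pHthr[d2] <- cfg$p_H_norm
          st$pP[d2] <- cfg$p_P_norm; st$pPeff[d2] <- cfg$p_P_norm
          st$bound[d2] <- 0; st$clone[d2] <- 0L
          st$Dt[d2] <- cfg$tau_min; st$quies[d2] <- FALSE
        }
      }
    }
  }

  ## --- necrotic turnover --------------------------------------------------
  nec <- which(st$kind == 3L)
  if (length(nec)) {
    st$kind[nec[necrotic_turnover(length(nec), dt, cfg)]] <- 0L
  }

  ## --- vasculature --------------------------------------------------------
  hyp <- which(as.vector(st$O) < cfg$k_O)
  exposed <- if (nrow(st$vessels)) {
    kindpad <- c(st$kind, 0L)
    rowSums(matrix(kindpad[st$NB[st$vessels$site, , drop = FALSE]] == 1L,
                   nrow = nrow(st$vessels))) > 0L |
      st$kind[st$vessels$site] == 1L
  } else logical(0)
  st$vessels <- update_vessels(st$vessels, hyp, cfg, dt, exposed)

  ## --- immune -------------------------------------------------------------
  tc_occ <- logical(n + 1L)
  tc_occ[st$tc_site] <- TRUE
  n_tumor <- sum(st$kind == 1L)
  free_vs <- st$vessels$site[st$kind[st$vessels$site] != 1L &
                               !tc_occ[st$vessels$site]]
  rec <- recruit_tcells(n_tumor, st$t, free_vs, cfg, dt, st$deferred)
  st$deferred <- rec$deferred
  if (length(rec$sites)) {
    st$tc_site <- c(st$tc_site, rec$sites)
    st$tc_state <- c(st$tc_state, rep(1L, length(rec$sites)))
    st$tc_timer <- c(st$tc_timer, rep(0, length(rec$sites)))
    st$tc_target <- c(st$tc_target, rep(0L, length(rec$sites)))
    st$tc_age <- c(st$tc_age, rep(0, length(rec$sites)))
    tc_occ[rec$sites] <- TRUE
  }
  ntc <- length(st$tc_site)
  if (ntc) {
    Gv <- as.vector(st$G)
    ## engaged: count down and resolve
    eng <- st$tc_state == 2L
    st$tc_timer[eng] <- st$tc_timer[eng] - dt
    res <- which(eng & st$tc_timer <= 0)
    if (length(res)) {
      tgt <- st$tc_target[res]
      still <- st$kind[tgt] == 1L
      pk <- kill_probability(st$pPeff[tgt], cfg$p_P_min)
      kill <- still & stats::runif(length(res)) < pk
      ks <- unique(tgt[kill])
      if (length(ks)) {
        st$kill_log[[length(st$kill_log) + 1L]] <- tibble::tibble(
          time = st$t + dt,
          x = ((ks - 1L) %% st$nx) + 1L, y = ((ks - 1L) %/% st$nx) + 1L,
          clone_id = st$clone[ks], P_k = kill_probability(st$pPeff[ks],
                                                          cfg$p_P_min))
        st$kind[ks] <- 0L                 # cytotoxic clearance is immediate
        st$clone[ks] <- 0L
        st$n_kills <- st$n_kills + length(ks)
      }
      st$tc_state[res] <- 1L
      st$tc_target[res] <- 0L
      st$tc_timer[res] <- 0
    }
    ## glucose-scaled baseline death (free and inactivated)
    mobile <- st$tc_state != 2L
    pdie <- 1 - exp(-tcell_death_rate(Gv[st$tc_site], cfg) * dt)
    dead <- mobile & stats::runif(ntc) < pdie
    if (any(dead)) {
      keep <- !dead
      st$tc_site <- st$tc_site[keep]; st$tc_state <- st$tc_state[keep]
      st$tc_timer <- st$tc_timer[keep]; st$tc_target <- st$tc_target[keep]
      st$tc_age <- st$tc_age[keep]
      ntc <- length(st$tc_site)
    }
    if (ntc) {
      tc_occ <- logical(n + 1L)
      tc_occ[st$tc_site] <- TRUE
      kindpad <- c(st$kind, 9L)
      ## random-walk motility
      mv <- which(st$tc_state != 2L & stats::runif(ntc) < cfg$T_M)
      if (length(mv)) {
        nbm <- st$NB[st$tc_site[mv], , drop = FALSE]
        # T-cells migrate through stroma (normal/necrotic sites) but may not
        # co-occupy tumor-cell sites or other T-cells' sites
        valid <- matrix(kindpad[nbm] != 1L & kindpad[nbm] != 9L &
                          !tc_occ[nbm], nrow = length(mv))
        pick <- pick_random_col(valid)
        dest <- integer(length(mv))
        dest[pick > 0] <- nbm[cbind(which(pick > 0), pick[pick > 0])]
        perm <- sample.int(length(mv))
        ok <- logical(length(mv))
        ok[perm] <- pick[perm] > 0 & !duplicated(dest[perm]) & dest[perm] > 0
        if (any(ok)) {
          tc_occ[st$tc_site[mv[ok]]] <- FALSE
          st$tc_site[mv[ok]] <- dest[ok]
          tc_occ[dest[ok]] <- TRUE
        }
      }
      ## contact: acid-inactivation test, else engage a random tumor neighbor
      fr <- which(st$tc_state == 1L)
      if (length(fr)) {
        nbm <- st$NB[st$tc_site[fr], , drop = FALSE]
        tumor_nb <- matrix(kindpad[nbm] == 1L, nrow = length(fr))
        has <- rowSums(tumor_nb) > 0L
        ci <- which(has)
        if (length(ci)) {
          ph_tc <- pH_site[st$tc_site[fr[ci]]]
          pai <- acid_inactivation_prob(ph_tc, cfg$H_p, cfg$sigma_p)
          inact <- stats::runif(length(ci)) < pai
          if (cfg$inactivation_permanent && any(inact)) {
            st$tc_state[fr[ci[inact]]] <- 3L
          }
          egi <- ci[!inact]
          if (length(egi)) {
            pickt <- pick_random_col(tumor_nb[egi, , drop = FALSE])
            sel <- pickt > 0
            if (any(sel)) {
              rows <- egi[sel]
              tsite <- nbm[cbind(rows, pickt[sel])]
              idx <- fr[rows]
              st$tc_state[idx] <- 2L
              st$tc_target[idx] <- tsite
              st$tc_timer[idx] <- engagement_duration(
                pH_site[st$tc_site[idx]], cfg$d_e, cfg$H_e, cfg$sigma_e)
            }
          }
        }
      }
      ## interaction stamping: every traversed neighborhood, any T-cell state
      stamp <- unique(c(st$tc_site, as.vector(st$NB[st$tc_site, ,
                                                    drop = FALSE])))
      stamp <- stamp[stamp <= n]
      st$Tlast <- update_interaction_grid(st$Tlast, stamp, st$t + dt)
      st$tc_age <- st$tc_age + dt
    }
  }

  ## --- bound PD-L1 --------------------------------------------------------
  li <- which(st$kind == 1L | st$kind == 2L)
  if (length(li)) {
    ub <- update_bound_pdl1(st$bound[li], st$pP[li],
                            as.vector(st$A)[li], cfg, dt)
    st$bound[li] <- ub$bound
    st$pPeff[li] <- ub$p_P_eff
  }

  st$t <- st$t + dt
  invisible(st)
}

# Metaphenotype inputs + classification for all tumor cells at current state.
compute_mp <- function(st, cfg, p_R_vessel) {
  ti <- which(st$kind == 1L)
  if (!length(ti)) {
    return(list(sites = integer(),
                mp = classify_metaphenotypes(numeric(0), numeric(0),
                                             numeric(0), numeric(0),
                                             numeric(0), numeric(0),
                                             cfg$tau_min, numeric(0))))
  }
  pHs <- -log10(as.vector(st$Hp)[ti])
  I <- interaction_indicator(st$Tlast[ti], st$t, cfg$T_w)
  P_k <- kill_probability(st$pPeff[ti], cfg$p_P_min)
  P_AI <- acid_inactivation_prob(pHs, cfg$H_p, cfg$sigma_p)
  pbar <- normalized_production(st$pR[ti], p_R_vessel)
  S <- glucose_survival(as.vector(st$G)[ti], cfg$L_i, cfg$L_0, cfg$L_g,
                        cfg$G_0, cfg$g_floor)
  P_g <- 1 - S / 100
  nbv <- ifelse(st$kind == 1L | st$kind == 2L, st$pPeff / cfg$p_P_min, 0)
  nbv <- c(nbv, 0)
  mx <- row_max_nb(nbv, st$NB[ti, , drop = FALSE])
  mx[!is.finite(mx)] <- 0
  mp <- classify_metaphenotypes(I, P_k, P_AI, pbar, P_g, st$Dt[ti],
                                cfg$tau_min, mx)
  list(sites = ti, mp = mp)
}

record_state <- function(st, cfg, params, p_R_vessel) {
  ti <- st$kind == 1L
  n_t <- sum(ti)
  cmp <- compute_mp(st, cfg, p_R_vessel)
  mp_sums <- colSums(as.matrix(cmp$mp))
  if (!length(cmp$sites)) mp_sums <- stats::setNames(rep(0, 7),
                                                     paste0("MP", 1:7))
  ts <- tibble::tibble(
    time = st$t,
    n_tumor = n_t,
    n_normal = sum(st$kind == 2L),
    n_necrotic = sum(st$kind == 3L),
    tumor_area_mm2 = n_t * (cfg$dx / 1000)^2,
    lesion_area_mm2 = (n_t + sum(st$kind == 3L)) * (cfg$dx / 1000)^2,
    mean_pG = if (n_t) mean(st$pG[ti]) else NA_real_,
    mean_pH = if (n_t) mean(st$pHthr[ti]) else NA_real_,
    mean_pP = if (n_t) mean(st$pP[ti]) else NA_real_,
    mean_pP_eff = if (n_t) mean(st$pPeff[ti]) else NA_real_,
    n_tcell_free = sum(st$tc_state == 1L),
    n_tcell_engaged = sum(st$tc_state == 2L),
    n_tcell_inactivated = sum(st$tc_state == 3L),
    n_vessels = nrow(st$vessels),
    n_kills_cum = st$n_kills,
    min_pH_env = -log10(max(st$Hp)),
    buffer_B = buffer_level(cfg$treatment, st$t),
    anti_pdl1_on = antipdl1_active(cfg$treatment, st$t))
  lin <- NULL
  if (n_t) {
    cl <- st$clone[ti]
    agg <- rowsum(cbind(1, st$pG[ti], st$pHthr[ti], st$pP[ti]), cl)
    ids <- as.integer(rownames(agg))
    lin <- tibble::tibble(
      time = st$t, clone_id = ids,
      parent_id = st$clone_parent[ids],
      n_cells = as.integer(agg[, 1]),
      mean_pG = agg[, 2] / agg[, 1],
      mean_pH = agg[, 3] / agg[, 1],
      mean_pP = agg[, 4] / agg[, 1])
  }
  list(ts = ts,
       mp = tibble::as_tibble(c(list(time = st$t), as.list(mp_sums))),
       lineage = lin)
}

cells_tibble <- function(st) {
  idx <- which(st$kind != 0L)
  tibble::tibble(
    site = idx,
    x = ((idx - 1L) %% st$nx) + 1L,
    y = ((idx - 1L) %/% st$nx) + 1L,
    kind = c("tumor", "normal", "necrotic")[st$kind[idx]],
    p_G = st$pG[idx], p_H = st$pHthr[idx], p_P = st$pP[idx],
    bound_pdl1 = st$bound[idx], p_P_eff = st$pPeff[idx],
    D = st$Dt[idx], quiescent = st$quies[idx], clone_id = st$clone[idx])
}

tcells_tibble <- function(st) {
  tibble::tibble(
    site = st$tc_site,
    x = ((st$tc_site - 1L) %% st$nx) + 1L,
    y = ((st$tc_site - 1L) %/% st$nx) + 1L,
    state = c("free", "engaged", "inactivated")[st$tc_state],
    age = st$tc_age)
}

#' Run a full simulation
#'
#' Executes the hybrid loop for `cfg$duration` days: solve the diffusible
#' fields to quasi-steady state, metabolize cells and apply ATP/acid-gated
#' fate, progress and divide tumor cells with heritable phenotype drift, turn
#' over necrotic debris, collapse/renew vessels, recruit and step T-cells
#' (motility, acid inactivation, PD-L1-gated killing, glucose-scaled decay),
#' update drug binding, and record time series, lineages, and metaphenotype
#' expression. Runs are bitwise reproducible given the same configuration and
#' seed.
#'
#' @param cfg An [sim_config()]; `cfg$seed` seeds every random draw.
#' @param tumor Optional initial tumor layout tibble (see
#'   [make_fig1_fixture()]); default is a central disc.
#' @return An object of class `mp_sim`: a list with `config`, `p_R_vessel`,
#'   `timeseries`, `mp_timeseries` (per-record expression sums), `lineage`,
#'   `kill_log`, final `cells`, `tcells`, `vessels`, `fields`, and `mp_final`
#'   (the per-cell metaphenotype table at the horizon).
#' @export
run_simulation <- function(cfg, tumor = NULL) {
  validate_sim_config(cfg)
  set.seed(cfg$seed)
  params <- metabolism_params(cfg)
  p_R_vessel <- calibrate_vessel_buffering(cfg)
  st <- initial_state(cfg, tumor)
  solve_state_fields(st, cfg, params)
  recs <- list(record_state(st, cfg, params, p_R_vessel))
  nsteps <- round(cfg$duration / cfg$dt)
  rec_steps <- max(1L, round(cfg$record_every / cfg$dt))
  for (i in seq_len(nsteps)) {
    advance_step(st, cfg, params, step_i = i)
    st$t <- i * cfg$dt            # anchor time to the step grid (no fp drift)
    if (i %% rec_steps == 0L || i == nsteps) {
      recs[[length(recs) + 1L]] <- record_state(st, cfg, params, p_R_vessel)
    }
  }
  cmp <- compute_mp(st, cfg, p_R_vessel)
  mp_final <- if (length(cmp$sites)) {
    dplyr::bind_cols(
      tibble::tibble(site = cmp$sites,
                     x = ((cmp$sites - 1L) %% st$nx) + 1L,
                     y = ((cmp$sites - 1L) %/% st$nx) + 1L,
                     clone_id = st$clone[cmp$sites]),
      cmp$mp)
  } else {
    dplyr::bind_cols(tibble::tibble(site = integer(), x = integer(),
                                    y = integer(), clone_id = integer()),
                     cmp$mp)
  }
  lineage <- dplyr::bind_rows(purrr::compact(purrr::map(recs, "lineage")))
  structure(list(
    config = cfg,
    p_R_vessel = p_R_vessel,
    timeseries = dplyr::bind_rows(purrr::map(recs, "ts")),
    mp_timeseries = dplyr::bind_rows(purrr::map(recs, "mp")),
    lineage = lineage,
    kill_log = if (length(st$kill_log)) dplyr::bind_rows(st$kill_log)
    else tibble::tibble(time = numeric(), x = integer(), y = integer(),
                        clone_id = integer(), P_k = numeric()),
    cells = cells_tibble(st),
    tcells = tcells_tibble(st),
    vessels = st$vessels,
    fields = structure(list(oxygen = st$O, glucose = st$G, protons = st$Hp,
                            drug = st$A), class = "mp_fields"),
    mp_final = mp_final),
    class = "mp_sim")
}

#' @export
print.mp_sim <- function(x, ...) {
  fin <- x$timeseries[nrow(x$timeseries), ]
  cat("<mp_sim> ", x$config$grid_width, "x", x$config$grid_height,
      " lattice, ", max(x$timeseries$time), " days simulated\n", sep = "")
  cat(sprintf(
    "  final: %d tumor cells (%.3f mm2), %d T-cells, %d vessels, %d kills\n",
    fin$n_tumor, fin$tumor_area_mm2,
    fin$n_tcell_free + fin$n_tcell_engaged + fin$n_tcell_inactivated,
    fin$n_vessels, fin$n_kills_cum))
  cat(sprintf("  mean phenotypes: p_G = %.2f, p_H = %.3f, p_P = %.2f\n",
              fin$mean_pG, fin$mean_pH, fin$mean_pP))
  invisible(x)
}
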