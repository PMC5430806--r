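#' Configuration for the synthetic mote-study generator
#'
#' Bundles every knob of the synthetic data generator: study design (camps,
#' camp sizes, days, 2-minute slots, the 05:00--20:00 daytime window), the
#' dyadic contact process (a per-slot Bernoulli detection whose probability
#' is a base rate scaled up for household co-members and kin and by the two
#' individuals' gregariousness), and the planted outcome effects used for
#' parameter-recovery studies. All planted effect sizes are in per-two-SD
#' standardized units, i.e. they are the coefficients the downstream
#' standardized regressions estimate.
#'
#' @param n_camps number of camps.
#' @param camp_size_range integer pair, inclusive range of camp sizes
#'   (minimum 2).
#' @param study_days days each camp is observed (the field protocol ranged
#'   over five to nine days).
#' @param slot_minutes ping interval in minutes (the motes emit every two
#'   minutes).
#' @param day_window clock-hour pair; detections are analysed for slot
#'   starts in `[day_window[1], day_window[2])`, default 05:00--20:00.
#' @param base_rate per-slot detection probability for an unrelated,
#'   average-gregariousness dyad.
#' @param household_boost,kin_boost multiplicative rate factors (>= 1) for
#'   same-household and kin-flagged dyads.
#' @param kin_fraction fraction of cross-household dyads flagged as kin.
#' @param gregariousness_sd SD of log individual gregariousness; each
#'   dyad's rate is multiplied by `g_i * g_j`.
#' @param household_size target household size used when partitioning a
#'   camp into households.
#' @param mother_fraction,child_fraction camp composition fractions; every
#'   camp gets at least five mothers, children are under 12 and are
#'   excluded from networks downstream.
#' @param late_fraction fraction of individuals whose presence interval is
#'   truncated (late arrival or early departure), emulating people joining
#'   or leaving camp mid-study.
#' @param drop_prob probability that one *direction* of a detection is lost
#'   (asymmetric radio loss); both directions are dropped independently.
#' @param beta_centrality_fertility planted fertility effect of the
#'   realized camp-standardized centrality named in `fertility_measure`,
#'   per two SD, additive on the expected offspring count.
#' @param fertility_measure which centrality measure carries the planted
#'   fertility effect.
#' @param beta_age_interaction planted centrality-by-age interaction
#'   (both columns two-SD standardized).
#' @param beta_closeness_sickness planted direct effect of two-SD
#'   standardized closeness on the expected sickness count.
#' @param beta_dependents_sickness planted effect of the (centered) number
#'   of dependents on the expected sickness count.
#' @param beta_dependents_betweenness planted effect, on the expected
#'   offspring count, of the component of two-SD standardized betweenness
#'   orthogonal to closeness; this is the mediated pathway used by the
#'   mediation scenario (see the vignette for why it is orthogonalized).
#' @param fertility_curve named triple `(a, b, c)`: log-scale baseline
#'   fertility `mu0(age) = exp(a + b*age + c*age^2)`. The default peaks
#'   around 6 living offspring at age 45 and stays above 2 across 15--75,
#'   in line with high-fertility forager demography.
#' @param sickness_base baseline expected sickness count (the survey
#'   records 0--2 instances over two weeks).
#' @param start study start (date or POSIXct, UTC midnight).
#' @param population population label attached to all records.
#' @param seed integer RNG seed; every generator function derives its
#'   stream from it, so identical configs give byte-identical output.
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_population()], [simulate_ping_log()],
#'   [simulate_dyad_counts()], [simulate_outcomes()], [simulate_study()]
#' @export
sim_config <- function(n_camps = 3,
                       camp_size_range = c(18, 24),
                       study_days = 7,
                       slot_minutes = 2,
                       day_window = c(5, 20),
                       base_rate = 0.002,
                       household_boost = 10,
                       kin_boost = 3,
                       kin_fraction = 0.05,
                       gregariousness_sd = 0.6,
                       household_size = 4,
                       mother_fraction = 1 / 3,
                       child_fraction = 1 / 4,
                       late_fraction = 0.2,
                       drop_prob = 0.1,
                       beta_centrality_fertility = 0,
                       fertility_measure = "betweenness",
                       beta_age_interaction = 0,
                       beta_closeness_sickness = 0,
                       beta_dependents_sickness = 0,
                       beta_dependents_betweenness = 0,
                       fertility_curve = c(a = -0.678, b = 0.1098, c = -0.00122),
                       sickness_base = 0.6,
                       start = "2014-03-01",
                       population = "A",
                       seed = 1L) {
  camp_size_range <- as.integer(round(camp_size_range))
  if (length(camp_size_range) != 2 || any(camp_size_range < 2))
    stop("invalid config: camp_size_range must be a pair of counts >= 2")
  if (camp_size_range[1] > camp_size_range[2])
    stop("invalid config: camp_size_range must be increasing")
  if (study_days < 1) stop("invalid config: study_days must be >= 1")
  for (p in c(base_rate, drop_prob, kin_fraction, late_fraction,
              mother_fraction, child_fraction)) {
    if (p < 0 || p > 1) stop("invalid config: probabilities must lie in [0, 1]")
  }
  if (household_boost < 1 || kin_boost < 1)
    stop("invalid config: household_boost and kin_boost must be >= 1")
  if (day_window[1] >= day_window[2] || day_window[1] < 0 || day_window[2] > 24)
    stop("invalid config: day_window must be an increasing clock-hour pair")
  stopifnot(length(fertility_curve) == 3)
  cfg <- list(
    n_camps = as.integer(n_camps),
    camp_size_range = camp_size_range,
    study_days = as.integer(study_days),
    slot_minutes = slot_minutes,
    day_window = day_window,
    base_rate = base_rate,
    household_boost = household_boost,
    kin_boost = kin_boost,
    kin_fraction = kin_fraction,
    gregariousness_sd = gregariousness_sd,
    household_size = household_size,
    mother_fraction = mother_fraction,
    child_fraction = child_fraction,
    late_fraction = late_fraction,
    drop_prob = drop_prob,
    beta_centrality_fertility = beta_centrality_fertility,
    fertility_measure = match.arg(fertility_measure,
      c("degree", "strength", "ec", "betweenness", "closeness")),
    beta_age_interaction = beta_age_interaction,
    beta_closeness_sickness = beta_closeness_sickness,
    beta_dependents_sickness = beta_dependents_sickness,
    beta_dependents_betweenness = beta_dependents_betweenness,
    fertility_curve = unname(fertility_curve),
    sickness_base = sickness_base,
    start_time = .as_utc(paste(start, "00:00:00")),
    population = population,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic mote-study configuration\n")
  cat(sprintf("  %d camp(s) of %d-%d people, %d day(s), %g-min slots, window %02d:00-%02d:00\n",
              x$n_camps, x$camp_size_range[1], x$camp_size_range[2],
              x$study_days, x$slot_minutes, x$day_window[1], x$day_window[2]))
  cat(sprintf("  contact: base %g/slot, household x%g, kin x%g, log-greg SD %g, drop %g\n",
              x$base_rate, x$household_boost, x$kin_boost,
              x$gregariousness_sd, x$drop_prob))
  cat(sprintf("  planted: fertility %g (%s), age-int %g, closeness->sickness %g, dependents->sickness %g\n",
              x$beta_centrality_fertility, x$fertility_measure,
              x$beta_age_interaction, x$beta_closeness_sickness,
              x$beta_dependents_sickness))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Simulate a multi-camp population with presence intervals
#'
#' Draws camp rosters (id, camp, age, sex, household, mother flag,
#' gregariousness, camp-level `settled` flag, individual `mobile` flag and a
#' `belongings` wealth score) and one presence interval per individual.
#' Ages span roughly 1--75: mothers are 17--55, other adolescents/adults
#' 12--75 and children 1--11. Every camp contains at least five mothers. A
#' `late_fraction` of individuals either arrive after the study starts or
#' leave before it ends; presence endpoints are aligned to the slot grid.
#'
#' Offspring, dependents and sickness counts are left `NA`; they are
#' planted on realized network centrality by [simulate_outcomes()].
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_population`: a list with data frames
#'   `roster`, `presence` (`individual, camp, enter, exit`), `kin`
#'   (`camp, id_a, id_b`), and the `config`.
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  start <- config$start_time
  end <- start + config$study_days * 86400
  rosters <- vector("list", config$n_camps)
  presences <- vector("list", config$n_camps)
  kins <- vector("list", config$n_camps)

  for (k in seq_len(config$n_camps)) {
    camp <- sprintf("camp%02d", k)
    lo <- config$camp_size_range[1]
    hi <- config$camp_size_range[2]
    size <- if (lo == hi) lo else sample(seq(lo, hi), 1L)
    n_mothers <- min(size, max(5L, as.integer(round(size * config$mother_fraction))))
    n_children <- min(size - n_mothers,
                      as.integer(round(size * config$child_fraction)))
    n_other <- size - n_mothers - n_children
    role <- c(rep("mother", n_mothers), rep("child", n_children),
              rep("other", n_other))
    age <- numeric(size)
    age[role == "mother"] <- runif(n_mothers, 17, 55)
    age[role == "child"] <- runif(sum(role == "child"), 1, 11)
    age[role == "other"] <- runif(sum(role == "other"), 12, 75)
    sex <- ifelse(role == "mother", "F",
                  ifelse(runif(size) < 0.5, "F", "M"))
    # households of variable size (Poisson around the target), as in real
    # camps where nuclear families differ in size
    hh_sizes <- integer(0)
    while (sum(hh_sizes) < size) {
      hh_sizes <- c(hh_sizes, max(2L, rpois(1L, config$household_size)))
    }
    hh <- sample(rep(seq_along(hh_sizes), hh_sizes)[seq_len(size)])
    settled <- rbinom(1L, 1L, 0.5)
    ids <- sprintf("%s_i%03d", camp, seq_len(size))
    rosters[[k]] <- data.frame(
      id = ids,
      camp_id = camp,
      population = config$population,
      age = round(age, 1),
      sex = sex,
      household_id = sprintf("%s_h%02d", camp, hh),
      is_mother = role == "mother",
      gregariousness = exp(rnorm(size, 0, config$gregariousness_sd)),
      settled = settled,
      mobile = rbinom(size, 1L, 0.3),
      belongings = round(rlnorm(size, 0, 0.5), 2),
      n_living_offspring = NA_integer_,
      n_dependents = NA_integer_,
      sickness_count = NA_integer_,
      stringsAsFactors = FALSE
    )

    # presence: full study period, truncated for a late/early fraction
    enter <- rep(start, size)
    exit <- rep(end, size)
    slot_sec <- config$slot_minutes * 60
    n_slots_total <- as.integer(config$study_days * 86400 / slot_sec)
    truncated <- which(runif(size) < config$late_fraction)
    for (i in truncated) {
      cut <- sample.int(floor(n_slots_total * 0.4), 1L) * slot_sec
      if (runif(1) < 0.5) enter[i] <- start + cut else exit[i] <- end - cut
    }
    presences[[k]] <- data.frame(
      individual = ids, camp = camp, enter = enter, exit = exit,
      stringsAsFactors = FALSE
    )

    # kin ties between households
    pairs <- which(upper.tri(matrix(0, size, size)), arr.ind = TRUE)
    cross <- hh[pairs[, 1]] != hh[pairs[, 2]]
    flag <- cross & runif(nrow(pairs)) < config$kin_fraction
    kins[[k]] <- data.frame(
      camp = rep(camp, sum(flag)),
      id_a = pmin(ids[pairs[flag, 1]], ids[pairs[flag, 2]]),
      id_b = pmax(ids[pairs[flag, 1]], ids[pairs[flag, 2]]),
      stringsAsFactors = FALSE
    )
  }

  out <- list(
    roster = do.call(rbind, rosters),
    presence = do.call(rbind, presences),
    kin = do.call(rbind, kins),
    config = config
  )
  rownames(out$roster) <- NULL
  rownames(out$presence) <- NULL
  rownames(out$kin) <- NULL
  class(out) <- "sim_population"
  out
}

# per-camp matrix of per-slot detection probabilities, clamped to [0, 1]
.dyad_rates <- function(roster_camp, kin_camp, config) {
  n <- nrow(roster_camp)
  g <- roster_camp$gregariousness
  same_hh <- outer(roster_camp$household_id, roster_camp$household_id, "==")
  kin <- matrix(FALSE, n, n)
  if (nrow(kin_camp) > 0) {
    ia <- match(kin_camp$id_a, roster_camp$id)
    ib <- match(kin_camp$id_b, roster_camp$id)
    kin[cbind(ia, ib)] <- TRUE
    kin[cbind(ib, ia)] <- TRUE
  }
  p <- config$base_rate *
    config$household_boost^same_hh *
    config$kin_boost^kin *
    outer(g, g)
  diag(p) <- 0
  pmin(pmax(p, 0), 1)
}

#' Simulate a directed mote ping log
#'
#' Runs the per-slot contact process: for every daytime slot in which a dyad
#' is co-present in camp, a symmetric detection occurs with probability
#' `p_ij = clamp(base_rate * household_boost^same_hh * kin_boost^kin *
#' g_i * g_j, 0, 1)`; when it occurs, each directed record ("i hears j",
#' "j hears i") is independently lost with probability `drop_prob`,
#' emulating asymmetric radio loss. Slots are independent; temporal
#' clustering of contacts is deliberately not modelled.
#'
#' This is the record-level generator used for round-trip and determinism
#' tests; replicate studies use the distributionally equivalent count-level
#' shortcut [simulate_dyad_counts()].
#'
#' @param pop a [simulate_population()] result.
#' @param config the same [sim_config()].
#' @return data frame `emitter, receiver, timestamp`, sorted by time.
#' @export
simulate_ping_log <- function(pop, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(config$seed + 1L)
  start <- config$start_time
  end <- start + config$study_days * 86400
  grid <- .daytime_slot_grid(start, end, config$slot_minutes, config$day_window)
  grid_min <- .abs_minutes(grid)
  out <- list()
  for (camp in unique(pop$roster$camp_id)) {
    rc <- pop$roster[pop$roster$camp_id == camp, , drop = FALSE]
    prc <- pop$presence[pop$presence$camp == camp, , drop = FALSE]
    prc <- prc[match(rc$id, prc$individual), , drop = FALSE]
    kc <- pop$kin[pop$kin$camp == camp, , drop = FALSE]
    p <- .dyad_rates(rc, kc, config)
    ent <- .abs_minutes(prc$enter)
    ext <- .abs_minutes(prc$exit)
    n <- nrow(rc)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (p[i, j] <= 0) next
        lo <- max(ent[i], ent[j])
        hi <- min(ext[i], ext[j])
        if (hi <= lo) next
        sl <- grid_min >= lo & grid_min < hi
        if (!any(sl)) next
        hit <- which(sl)[runif(sum(sl)) < p[i, j]]
        if (!length(hit)) next
        keep_ij <- runif(length(hit)) >= config$drop_prob
        keep_ji <- runif(length(hit)) >= config$drop_prob
        ts <- grid[c(hit[keep_ij], hit[keep_ji])]
        if (!length(ts)) next
        out[[length(out) + 1L]] <- data.frame(
          emitter = c(rep(rc$id[j], sum(keep_ij)), rep(rc$id[i], sum(keep_ji))),
          receiver = c(rep(rc$id[i], sum(keep_ij)), rep(rc$id[j], sum(keep_ji))),
          timestamp = ts,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    return(data.frame(emitter = character(0), receiver = character(0),
                      timestamp = .as_utc(character(0))))
  }
  log <- do.call(rbind, out)
  log <- log[order(log$timestamp, log$emitter, log$receiver), , drop = FALSE]
  rownames(log) <- NULL
  log
}

#' Simulate dyad-slot event counts directly
#'
#' Count-level equivalent of [simulate_ping_log()] followed by daytime
#' filtering and collapse to dyad-slot events: for each dyad the number of
#' detected slots is `Binomial(n_copresent_daytime_slots, p_eff)` with
#' `p_eff = p_ij * (1 - drop_prob^2)` under one-sided collapse (an event
#' survives if at least one direction survives) or
#' `p_ij * (1 - drop_prob)^2` under reciprocal collapse. Used by replicate
#' studies where only the per-dyad counts matter.
#'
#' @inheritParams simulate_ping_log
#' @param mode `"one_sided"` (default) or `"reciprocal"`, matching the
#'   collapse convention of [collapse_to_dyad_slots()].
#' @return data frame `camp, id_a, id_b, events, overlap_hours`.
#' @export
simulate_dyad_counts <- function(pop, config = pop$config,
                                 mode = c("one_sided", "reciprocal")) {
  stopifnot(inherits(pop, "sim_population"))
  mode <- match.arg(mode)
  set.seed(config$seed + 1L)
  out <- list()
  for (camp in unique(pop$roster$camp_id)) {
    rc <- pop$roster[pop$roster$camp_id == camp, , drop = FALSE]
    prc <- pop$presence[pop$presence$camp == camp, , drop = FALSE]
    prc <- prc[match(rc$id, prc$individual), , drop = FALSE]
    kc <- pop$kin[pop$kin$camp == camp, , drop = FALSE]
    p <- .dyad_rates(rc, kc, config)
    surv <- if (mode == "one_sided") 1 - config$drop_prob^2
            else (1 - config$drop_prob)^2
    ent <- .abs_minutes(prc$enter)
    ext <- .abs_minutes(prc$exit)
    idx <- which(upper.tri(p), arr.ind = TRUE)
    i <- idx[, 1]
    j <- idx[, 2]
    lo <- pmax(ent[i], ent[j])
    hi <- pmin(ext[i], ext[j])
    n_slots <- .count_daytime_slots(lo * 60, hi * 60,
                                    config$slot_minutes, config$day_window)
    n_slots[hi <= lo] <- 0L
    events <- rbinom(length(i), n_slots, pmin(1, p[idx] * surv))
    out[[length(out) + 1L]] <- data.frame(
      camp = camp,
      id_a = pmin(rc$id[i], rc$id[j]),
      id_b = pmax(rc$id[i], rc$id[j]),
      events = events,
      overlap_hours = n_slots * config$slot_minutes / 60,
      stringsAsFactors = FALSE
    )
  }
  counts <- do.call(rbind, out)
  rownames(counts) <- NULL
  counts
}

#' Plant fertility and sickness outcomes on realized centrality
#'
#' Fills in mothers' `n_living_offspring`, `n_dependents` and
#' `sickness_count`. Effects are planted on the *realized* camp-standardized
#' centrality scores, two-SD standardized over the mother sample, so that
#' the coefficients the downstream standardized regressions estimate have
#' the planted values as exact targets:
#'
#' * offspring `~ Poisson(max(0.01, mu0(age) + b_f * x + b_int * x * a +
#'   b_med * xb_perp))` where `mu0(age) = exp(a0 + a1*age + a2*age^2)` is
#'   the quadratic baseline fertility curve, `x` is the standardized
#'   centrality named in `fertility_measure`, `a` is standardized age, and
#'   `xb_perp` is betweenness orthogonalized against closeness (the
#'   mediation pathway; zero unless `beta_dependents_betweenness` is set);
#' * `n_dependents` equals the living-offspring count;
#' * sickness `~ min(2, Poisson(max(0, s0 + b_c * x_closeness +
#'   b_d * (dependents - mean)))`, matching the 0--2 range of the
#'   two-week medical survey.
#'
#' @param pop a [simulate_population()] result.
#' @param centrality a [centrality_table()] for the simulated networks
#'   (z-columns are required).
#' @param config the same [sim_config()].
#' @return the roster with outcome columns filled for mothers.
#' @export
simulate_outcomes <- function(pop, centrality, config = pop$config) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(config$seed + 2L)
  roster <- pop$roster
  mothers <- which(roster$is_mother)
  idx <- match(roster$id[mothers], centrality$individual)
  if (anyNA(idx)) {
    stop("missing centrality for mother(s): ",
         paste(roster$id[mothers][is.na(idx)], collapse = ", "))
  }
  two_sd <- function(v) (v - mean(v)) / (2 * sd(v))
  zf <- centrality[[paste0("z_", config$fertility_measure)]][idx]
  x <- two_sd(zf)
  age <- roster$age[mothers]
  a_std <- two_sd(age)
  fc <- config$fertility_curve
  mu0 <- exp(fc[1] + fc[2] * age + fc[3] * age^2)
  rate <- mu0 + config$beta_centrality_fertility * x +
    config$beta_age_interaction * x * a_std
  if (config$beta_dependents_betweenness != 0) {
    xb <- two_sd(centrality$z_betweenness[idx])
    xc <- two_sd(centrality$z_closeness[idx])
    xb_perp <- stats::residuals(lm(xb ~ xc))
    rate <- rate + config$beta_dependents_betweenness * xb_perp
  }
  offspring <- rpois(length(mothers), pmax(rate, 0.01))
  roster$n_living_offspring[mothers] <- offspring
  roster$n_dependents[mothers] <- offspring

  xc_sick <- two_sd(centrality$z_closeness[idx])
  lam <- config$sickness_base +
    config$beta_closeness_sickness * xc_sick +
    config$beta_dependents_sickness * (offspring - mean(offspring))
  roster$sickness_count[mothers] <- pmin(2L, rpois(length(mothers), pmax(lam, 0)))
  roster
}

#' Write generator outputs in the ingest dialects
#'
#' `write_ping_log()` writes `emitter,receiver,timestamp` with ISO-8601
#' timestamps; `write_roster()` and `write_presence()` write the roster and
#' presence tables. These are the same dialects [read_ping_log()],
#' [read_roster()] and [read_presence()] parse, so generator output
#' round-trips losslessly.
#'
#' @param pings,roster,presence data frames as produced by the generator.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ping_log <- function(pings, path) {
  out <- data.frame(emitter = pings$emitter, receiver = pings$receiver,
                    timestamp = .format_iso(pings$timestamp))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ping_log
#' @export
write_roster <- function(roster, path) {
  write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ping_log
#' @export
write_presence <- function(presence, path) {
  out <- data.frame(individual = presence$individual, camp = presence$camp,
                    enter = .format_iso(presence$enter),
                    exit = .format_iso(presence$exit))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
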