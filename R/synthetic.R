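#' Toy networks with known attractor structure
#'
#' Small networks used as dynamics oracles and property-test substrates:
#' \describe{
#'   \item{`self_activator`}{one self-activating readout: bistable 1-D map
#'     with stable fixed points near 0 and 1 and an unstable point at 0.5;}
#'   \item{`toggle`}{two mutually inhibiting nodes (readout `ACAN` vs
#'     `MMP13`): the classic bistable toggle, basin boundary on the
#'     diagonal;}
#'   \item{`cascade`}{monotone activating chain `X -> M -> ACAN`: the
#'     ensemble-mean readout is non-decreasing in the clamp on `X`;}
#'   \item{`switch`}{an IL4-type switch whose majority label flips exactly
#'     at a planted clamp value (see `flip`): `ACAN` driven by `IL4` and a
#'     basal `ECM` drive. The returned `truth$scan_clamps` holds the base
#'     clamps under which [find_critical_clamp()] on `IL4` recovers `flip`.}
#' }
#'
#' @param motif one of `"self_activator"`, `"toggle"`, `"cascade"`,
#'   `"switch"`.
#' @param flip planted critical clamp value in (0,1) for the `switch` motif.
#' @return list with elements `network` (an `rnm_network`) and `truth`
#'   (motif-specific bookkeeping: planted flip value, scan clamps, basin
#'   fractions where known).
#' @export
make_toy_network <- function(motif = c("self_activator", "toggle",
                                       "cascade", "switch"),
                             flip = 0.3) {
  motif <- match.arg(motif)
  ed <- function(s, t, sg, w = 1) {
    data.frame(source = s, target = t, sign = sg, weight = w,
               stringsAsFactors = FALSE)
  }
  if (motif == "self_activator") {
    net <- rnm_network(ed("ACAN", "ACAN", 1))
    truth <- list(fixed_points = c(0, 0.5, 1), stable = c(TRUE, FALSE, TRUE),
                  basin_anabolic = 0.5)
  } else if (motif == "toggle") {
    net <- rnm_network(rbind(ed("ACAN", "MMP13", -1), ed("MMP13", "ACAN", -1)))
    truth <- list(n_attractors = 2, basin_anabolic = 0.5)
  } else if (motif == "cascade") {
    net <- rnm_network(rbind(ed("X", "M", 1), ed("M", "ACAN", 1)),
                       nodes = data.frame(node = c("X", "M", "ACAN"),
                                          role = c("cytokine", "generic",
                                                   "readout")))
    truth <- list(monotone_in = "X")
  } else {
    stopifnot(flip > 0, flip < 1)
    net <- rnm_network(
      rbind(ed("IL4", "ACAN", 1, 1), ed("ECM", "ACAN", 1, 1.2)),
      nodes = data.frame(node = c("IL4", "ECM", "ACAN"),
                         role = c("cytokine", "ecm", "readout")))
    truth <- list(flip = flip,
                  scan_clamps = c(ECM = (1.1 - flip) / 1.2),
                  scan_node = "IL4")
  }
  list(network = net, truth = truth)
}

#' Benchmark regulatory network with planted behavior
#'
#' A deterministic stand-in (synthetic, not the published chondrocyte
#' network) wired so that every built-in condition preset is runnable and
#' key behaviors are planted by construction:
#' mechanosensors `a5b1`, `avb3`, `TRPV4` drive `Actin`; `TNF` drives an
#' inflammatory hub `NFKB` that `Actin` suppresses (mechano-protection);
#' the readout `ACAN` integrates `IL4`, a bistable basal matrix drive
#' `ECM` and `TRPV4`, and is inhibited by `TNF` and `NFKB`; ten secreted
#' proteins hang off the hub (`IL6`, `IL8`, `IL17`, `LIF`, `IFNG`, `MMP3`,
#' `VEGF`, `NGF`, pro-inflammatory; `CCL2` suppressed by the hub; `TGFB`
#' following `ACAN`).
#'
#' Planted truths (returned in `truth`):
#' * clamping `TNF = 1` forces a pro-catabolic steady state in every run;
#' * under `truth$scan_clamps` the majority label flips exactly at
#'   `IL4 = flip` (`ACAN`'s input crosses 0.5 there), so
#'   [find_critical_clamp()] must recover `flip`;
#' * `truth$shared_analytes` names the panel analytes whose nodes the
#'   synthetic secretome shares with this network.
#'
#' @param flip planted IL4 critical clamp value in (0,1). Default 0.2585.
#' @return list with `network` (an `rnm_network`) and `truth`.
#' @export
make_benchmark_network <- function(flip = 0.2585) {
  stopifnot(flip > 0, flip < 1)
  ed <- function(s, t, sg, w = 1) {
    data.frame(source = s, target = t, sign = sg, weight = w,
               stringsAsFactors = FALSE)
  }
  hub_targets <- c("IL6", "IL8", "IL17", "LIF", "IFNG", "MMP3", "VEGF", "NGF")
  edges <- rbind(
    ed("a5b1", "Actin", 1), ed("avb3", "Actin", 1),
    ed("TNF", "NFKB", 1), ed("Actin", "NFKB", -1),
    ed("IL4", "ACAN", 1, 1), ed("ECM", "ACAN", 1, 1.2),
    ed("TRPV4", "ACAN", 1, 0.5),
    ed("TNF", "ACAN", -1), ed("NFKB", "ACAN", -1),
    do.call(rbind, lapply(hub_targets, function(t) ed("NFKB", t, 1))),
    ed("ECM", "CCL2", 1), ed("NFKB", "CCL2", -1),
    ed("ACAN", "TGFB", 1))
  nodes <- data.frame(
    node = c("a5b1", "avb3", "TRPV4", "TNF", "IL4", "ECM", "Actin", "NFKB",
             "ACAN", hub_targets, "CCL2", "TGFB"),
    role = c("mechanoreceptor", "mechanoreceptor", "mechanoreceptor",
             "cytokine", "cytokine", "ecm", "generic", "generic",
             "readout", rep("generic", length(hub_targets) + 2)),
    stringsAsFactors = FALSE)
  net <- rnm_network(edges, nodes)

  shared <- data.frame(
    analyte = c("IL-6", "IL-8", "IL-17", "LIF", "IFN-g", "MMP-3", "VEGF",
                "NGF", "CCL2", "TGF-b1"),
    node = c("IL6", "IL8", "IL17", "LIF", "IFNG", "MMP3", "VEGF", "NGF",
             "CCL2", "TGFB"),
    stringsAsFactors = FALSE)

  # with TRPV4 clamped 0.5 its contribution to ACAN's activator average
  # cancels, so the label flip sits exactly at IL4 = flip
  truth <- list(
    flip = flip,
    scan_node = "IL4",
    scan_clamps = c(ECM = (1.1 - flip) / 1.2, TRPV4 = 0.5,
                    a5b1 = 0.5, avb3 = 0.5, TNF = 0),
    forced_catabolic_clamp = c(TNF = 1),
    shared_analytes = shared)
  list(network = net, truth = truth)
}

#' Random signed network (for property tests)
#'
#' Seed-deterministic random signed, weighted network containing a readout
#' node `ACAN`; every node receives 1-2 regulators with mostly activating
#' signs and weights in (0.5, 1.5). Always passes [rnm_network()]
#' validation.
#'
#' @param n_nodes total node count (>= 2). Default 6.
#' @param seed integer seed.
#' @return an `rnm_network`.
#' @export
make_random_network <- function(n_nodes = 6, seed = NULL) {
  stopifnot(n_nodes >= 2)
  if (!is.null(seed)) set.seed(seed)
  nodes <- c("ACAN", sprintf("N%d", seq_len(n_nodes - 1)))
  edges <- do.call(rbind, lapply(nodes, function(tg) {
    k <- sample(1:2, 1)
    src <- sample(nodes, k)
    data.frame(source = src, target = tg,
               sign = ifelse(stats::runif(k) < 0.7, 1, -1),
               weight = stats::runif(k, 0.5, 1.5),
               stringsAsFactors = FALSE)
  }))
  rnm_network(edges)
}

# 73-analyte panel vocabulary (typical multiplex immunoassay names)
secretome_analyte_names <- function() {
  c("IL-6", "IL-8", "IL-17", "LIF", "IFN-g", "MMP-3", "VEGF", "NGF",
    "CCL2", "TGF-b1",
    "IL-1b", "RANTES", "ST2", "IL-9", "IL-13", "IL-18", "IL-22", "ICAM1",
    "VCAM1", "M-CSF", "MMP-9", "GROA", "CXCL9", "CXCL12", "CXCL13", "IP10",
    "DEFB1", "RETN", "MIF", "MMP-1", "MMP-2", "FST", "TNF10", "IL-4",
    "IL-10", "IL-15", "G-CSF", "GM-CSF", "CCL7", "CCL20", "S100A8", "CNTF",
    "IL-2RA", "CCL3", "CCL17", "TNFRSF9", "IL-5", "FGF-BASIC", "SCF",
    "sRANK-L", "PAI-1", "TNF", "SDF-1", "EGF", "HGF", "IGF-1", "PDGF-BB",
    "OPG", "OPN", "BMP-2", "BMP-7", "IL-1RA", "IL-7", "IL-12", "IL-21",
    "IL-23", "IL-31", "TSLP", "AREG", "EOTAXIN", "MCP-3", "TRAIL", "CXCL5")
}

default_analyte_classes <- function(analytes) {
  cls <- stats::setNames(rep("null", length(analytes)), analytes)
  up <- c("IL-6", "IL-8", "IL-1b", "RANTES", "ST2", "IL-9", "IL-13",
          "IL-18", "IL-22", "ICAM1", "VCAM1", "M-CSF", "MMP-9", "GROA",
          "CXCL9", "CXCL12", "CXCL13", "IP10", "DEFB1", "IFN-g")
  decay <- c("VEGF", "NGF", "RETN", "MIF", "MMP-1")
  absent <- c("IL-4", "GM-CSF", "CCL7")
  cls[intersect(up, analytes)] <- "tnf_up"
  cls["CCL2"] <- "tnf_down"
  cls[intersect(decay, analytes)] <- "time_decay"
  cls[intersect(absent, analytes)] <- "tnf_induced_absent"
  cls
}

#' Generate a synthetic Luminex-style secretome dataset
#'
#' Emulates the measurement structure of a multi-panel bead-based
#' immunoassay study: `n_analytes` proteins measured as MFI for
#' `n_donors` donors across four conditions (`control_unloaded`,
#' `control_dynamic`, `TNF_unloaded`, `TNF_dynamic`) and two sampling days,
#' with per-analyte blanks, an exact 8-point standard series, LOQ limits,
#' and a known 5PL response. Planted effects are expressed on the
#' LOQ-normalized \[0,1\] scale:
#' \describe{
#'   \item{`tnf_up` / `tnf_down`}{+`tnf_effect` / -`tnf_down_effect` under
#'     TNF;}
#'   \item{`time_decay`}{day-14 value drops by `decay_effect`;}
#'   \item{`tnf_induced_absent`}{zero concentration (below the lower LOQ)
#'     in control conditions, present under TNF;}
#'   \item{`null`}{no effect.}
#' }
#' Loading (unloaded vs dynamic) has no planted effect, mirroring the
#' experimental finding that dynamic compression left the secretome
#' unchanged. Noise is multiplicative log-normal on concentration: a
#' per-donor-per-analyte effect (`sigma_donor`) plus a per-measurement
#' residual (`sigma_resid`); standards and blanks are exact.
#'
#' @param seed integer seed (fully determines the dataset).
#' @param n_analytes number of analytes (<= 73). Default 73.
#' @param n_donors donors per condition. Default 5.
#' @param days sampling days. Default `c(7, 14)`.
#' @param tnf_effect,tnf_down_effect,decay_effect planted effect sizes on
#'   the normalized scale. Defaults 0.3, 0.25, 0.15.
#' @param sigma_donor,sigma_resid log-scale noise SDs. Defaults 0.2, 0.1.
#'   Set both to 0 for an exactly recoverable dataset.
#' @param planted optional data.frame `analyte, condition, x` overriding the
#'   planted normalized value of specific analyte/condition cells (applied
#'   to both days).
#' @param dir optional directory; when given the four panel CSVs are
#'   written there (see [write_secretome_panel()]).
#' @return list with `panel` (a `secretome_panel`) and `truth` (list:
#'   per-analyte `classes`, `curves` (true 5PL parameters, LOQs, blanks),
#'   `planted` (analyte x condition x day normalized values) and
#'   `referenced` (day-pooled, reference-subtracted truth values)).
#' @export
make_synthetic_secretome <- function(seed = 1, n_analytes = 73, n_donors = 5,
                                     days = c(7, 14), tnf_effect = 0.3,
                                     tnf_down_effect = 0.25,
                                     decay_effect = 0.15,
                                     sigma_donor = 0.2, sigma_resid = 0.1,
                                     planted = NULL, dir = NULL) {
  stopifnot(n_analytes >= 1, n_analytes <= 73, n_donors >= 1)
  set.seed(seed)
  analytes <- secretome_analyte_names()[seq_len(n_analytes)]
  conditions <- c("control_unloaded", "control_dynamic",
                  "TNF_unloaded", "TNF_dynamic")
  classes <- default_analyte_classes(analytes)

  curves <- data.frame(
    analyte = analytes,
    lloq = 10^stats::runif(n_analytes, -0.3, 0.7),
    A = stats::runif(n_analytes, 20, 60),
    D = stats::runif(n_analytes, 15000, 30000),
    B = stats::runif(n_analytes, 0.9, 1.6),
    G = stats::runif(n_analytes, 0.8, 1.25),
    blank = stats::runif(n_analytes, 15, 50),
    stringsAsFactors = FALSE)
  curves$uloq <- curves$lloq * 10^stats::runif(n_analytes, 2, 2.7)
  curves$C <- sqrt(curves$lloq * curves$uloq) *
    10^stats::runif(n_analytes, -0.2, 0.2)

  base <- stats::runif(n_analytes, 0.25, 0.45)
  grid <- expand.grid(analyte = analytes, condition = conditions, day = days,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  xt <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    an <- grid$analyte[i]
    b <- base[match(an, analytes)]
    tnf <- grepl("^TNF", grid$condition[i])
    xt[i] <- switch(classes[[an]],
      null = b,
      tnf_up = if (tnf) min(b + tnf_effect, 1) else b,
      tnf_down = if (tnf) max(b - tnf_down_effect, 0) else b,
      time_decay = max(b - if (grid$day[i] == max(days)) decay_effect else 0,
                       0),
      tnf_induced_absent = if (tnf) 0.35 else 0)
  }
  grid$x_true <- xt
  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      sel <- grid$analyte == planted$analyte[i] &
        grid$condition == planted$condition[i]
      if (!any(sel)) stop("planted override matches no cell: ",
                          planted$analyte[i], " / ", planted$condition[i])
      grid$x_true[sel] <- planted$x[i]
    }
  }

  donor_eff <- matrix(stats::rnorm(n_analytes * n_donors, 0, sigma_donor),
                      n_analytes, n_donors,
                      dimnames = list(analytes, NULL))

  meas <- merge(grid, data.frame(donor = seq_len(n_donors)))
  ci <- match(meas$analyte, analytes)
  conc_true <- curves$lloq[ci] + meas$x_true * (curves$uloq[ci] -
                                                  curves$lloq[ci])
  conc_true[meas$x_true == 0 &
              classes[meas$analyte] == "tnf_induced_absent"] <- 0
  noise <- exp(donor_eff[cbind(ci, meas$donor)] +
                 stats::rnorm(nrow(meas), 0, sigma_resid))
  conc_meas <- conc_true * noise
  meas$mfi <- pl5(conc_meas, curves$A[ci], curves$D[ci], curves$C[ci],
                  curves$B[ci], curves$G[ci]) + curves$blank[ci]

  standards <- do.call(rbind, lapply(seq_len(n_analytes), function(i) {
    conc <- exp(seq(log(curves$lloq[i] / 3), log(curves$uloq[i] * 3),
                    length.out = 8))
    data.frame(analyte = analytes[i], concentration = conc,
               mfi = pl5(conc, curves$A[i], curves$D[i], curves$C[i],
                         curves$B[i], curves$G[i]),
               stringsAsFactors = FALSE)
  }))

  panel <- secretome_panel(
    measurements = meas[, c("analyte", "donor", "condition", "day", "mfi")],
    standards = standards,
    blanks = data.frame(analyte = analytes, mfi = curves$blank),
    loq = curves[, c("analyte", "lloq", "uloq")])

  pooled <- stats::aggregate(x_true ~ analyte + condition, grid,
                             stats::median)
  ref <- pooled[pooled$condition == "control_unloaded",
                c("analyte", "x_true")]
  names(ref)[2] <- "x_reference"
  referenced <- merge(pooled, ref, by = "analyte")
  referenced$x_ref <- referenced$x_true - referenced$x_reference
  referenced$x_reference <- NULL
  names(referenced)[names(referenced) == "x_true"] <- "x"

  truth <- list(seed = seed, classes = classes, curves = curves,
                planted = grid, referenced = referenced,
                effects = list(tnf_effect = tnf_effect,
                               tnf_down_effect = tnf_down_effect,
                               decay_effect = decay_effect,
                               sigma_donor = sigma_donor,
                               sigma_resid = sigma_resid))
  if (!is.null(dir)) write_secretome_panel(panel, dir)
  list(panel = panel, truth = truth)
}

#' Jointly generated network + secretome fixture
#'
#' Builds the benchmark network, runs the four literature-derived condition
#' presets as seeded attractor ensembles, and generates a noiseless
#' synthetic secretome whose planted normalized values for the shared
#' analytes equal the ensemble-mean activations of the matching network
#' nodes. With no deviation the model-experiment concordance is therefore
#' exact (NMAD 0% in every condition); controlled disagreement can be
#' planted on top.
#'
#' @param seed integer seed; ensemble and secretome seeds are derived from
#'   it.
#' @param flip planted IL4 critical value passed to
#'   [make_benchmark_network()].
#' @param n ensemble size per condition. Default 100.
#' @param deviation optional list `(analyte =, condition =, delta =)`:
#'   adds `delta` to the planted secretome value of one shared analyte in
#'   one condition (the classic single-perturbation NMAD arithmetic:
#'   NMAD rises by `100 * delta / N` in that condition).
#' @param incongruent optional character vector of shared analytes whose
#'   secretome values are held at the control-unloaded level in the TNF
#'   conditions while the model responds (planted incongruence, the
#'   TGF-b/LIF/IL-8/IL-17 pattern).
#' @param params an [dynamics_params()] object.
#' @return list with `network`, `network_truth`, `ensembles` (named by
#'   condition label), `model_means` (node x condition), `panel`,
#'   `secretome_truth`, `calibrated_truth` (exact `calibrated_secretome`
#'   built from the planted values), `alias_map`, `shared`, and `seed`.
#' @export
make_paired_fixture <- function(seed = 1, flip = 0.2585, n = 100,
                                deviation = NULL, incongruent = NULL,
                                params = dynamics_params()) {
  bm <- make_benchmark_network(flip)
  shared <- bm$truth$shared_analytes
  presets <- builtin_presets()[c("lit_control_unloaded",
                                 "lit_control_dynamic",
                                 "lit_TNF_unloaded", "lit_TNF_dynamic")]
  conditions <- vapply(presets, preset_condition, "")
  ensembles <- stats::setNames(vector("list", length(presets)), conditions)
  for (i in seq_along(presets)) {
    ensembles[[i]] <- run_ensemble(bm$network, presets[[i]], n = n,
                                   seed = seed + i, params = params)
  }
  model_means <- vapply(ensembles, `[[`, ensembles[[1]]$mean_activation,
                        "mean_activation")

  planted <- do.call(rbind, lapply(conditions, function(cc) {
    data.frame(analyte = shared$analyte, condition = cc,
               x = unname(model_means[shared$node, cc]),
               stringsAsFactors = FALSE)
  }))
  if (!is.null(incongruent)) {
    bad <- setdiff(incongruent, shared$analyte)
    if (length(bad)) stop("incongruent analyte(s) not shared: ",
                          paste(bad, collapse = ", "))
    for (an in incongruent) {
      ctrl <- planted$x[planted$analyte == an &
                          planted$condition == "control_unloaded"]
      sel <- planted$analyte == an & grepl("^TNF", planted$condition)
      planted$x[sel] <- ctrl
    }
  }
  if (!is.null(deviation)) {
    sel <- planted$analyte == deviation$analyte &
      planted$condition == deviation$condition
    if (!any(sel)) stop("deviation target not found: ", deviation$analyte,
                        " / ", deviation$condition)
    planted$x[sel] <- planted$x[sel] + deviation$delta
    if (any(planted$x[sel] < 0 | planted$x[sel] > 1)) {
      stop("planted deviation leaves [0, 1]")
    }
  }

  sec <- make_synthetic_secretome(seed = seed + 100,
                                  sigma_donor = 0, sigma_resid = 0,
                                  planted = planted)

  ref_x <- planted$x[planted$condition == "control_unloaded"]
  names(ref_x) <- planted$analyte[planted$condition == "control_unloaded"]
  cal_truth <- data.frame(analyte = planted$analyte,
                          condition = planted$condition,
                          x = planted$x,
                          below_loq = FALSE, above_loq = FALSE,
                          stringsAsFactors = FALSE)
  cal_truth$x_ref <- cal_truth$x - ref_x[cal_truth$analyte]
  cal_truth <- structure(cal_truth,
                         class = c("calibrated_secretome", "data.frame"),
                         reference = "control_unloaded", pool_days = TRUE)

  list(network = bm$network, network_truth = bm$truth,
       ensembles = ensembles, model_means = model_means,
       panel = sec$panel, secretome_truth = sec$truth,
       calibrated_truth = cal_truth,
       alias_map = default_alias_map(), shared = shared, seed = seed)
}
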