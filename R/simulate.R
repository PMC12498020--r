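#' Describe a synthetic demographic scenario
#'
#' Populations drift from a shared ancestor under the Balding-Nichols
#' model: per SNP the ancestral frequency `p` is drawn from
#' `ancestral_freq_law` and each population's frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, so the drift parameter `F` plays the
#' role of the population's Fst from the ancestor. Admixed populations mix
#' source frequencies (`p_T = sum alpha_s p_s`), optionally with
#' post-admixture drift — frequency-level admixture, which reproduces the
#' f-statistic and PCA behaviour of admixed groups without a recombination
#' model. Diploid calls are `Binomial(2, p)` (pseudo-haploid: `0/2` only),
#' with uniform per-call missingness emulating ancient-DNA sparsity. An
#' optional planted signature shifts frequencies by `delta` at a small
#' random SNP subset for the affected populations only, creating a
#' low-variance differentiating component invisible on the top PCs.
#'
#' All randomness derives from the single integer `seed` through labelled
#' substreams ([substream_seed()]), so module order cannot change results.
#'
#' Populations may drift from the common ancestor or from another listed
#' population (`parent`), so nested tree topologies — a source and a
#' reference population sharing an internal branch, say — are expressible.
#' That matters for admixture modelling: a right panel only carries
#' information about mixture weights when its populations are
#' differentially related to the sources, which a pure star topology never
#' achieves. Internal branch populations can be declared with `n = 0`
#' (no samples drawn).
#'
#' @param n_snps number of SNPs.
#' @param populations data.frame with `label`, `fst` (drift parameter in
#'   (0, 1); ~0 means an undrifted copy of the parent), `n` (samples,
#'   >= 0) and optionally `parent` (another label, or `NA` for the
#'   common ancestor; parents must be listed before children).
#' @param admixture_events list of `list(target =, sources =, proportions =,
#'   post_drift = 0)`; targets must appear in `populations` (their `fst`
#'   is ignored in favour of `post_drift`).
#' @param missing_rate per-call missing probability (default 0.3, a typical
#'   ancient-DNA capture panel rate).
#' @param ancestral_freq_law `list(law = "uniform", min =, max =)` or
#'   `list(law = "beta", shape1 =, shape2 =)`.
#' @param signature optional `list(affected =, n_snps =, delta =)`.
#' @param pseudo_haploid emit `{0, 2}` calls only.
#' @param seed integer master seed.
#' @return A `scenario_spec`.
#' @export
scenario_spec <- function(n_snps, populations, admixture_events = list(),
                          missing_rate = 0.3,
                          ancestral_freq_law = list(law = "uniform",
                                                    min = 0.05, max = 0.95),
                          signature = NULL, pseudo_haploid = FALSE,
                          seed = 1) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "fst", "n") %in% names(populations)))
  if (is.null(populations$parent)) populations$parent <- NA_character_
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (any(populations$fst <= 0 | populations$fst >= 1)) {
    stop("drift parameters must lie in (0, 1)")
  }
  if (any(populations$n < 0)) stop("sample sizes must be >= 0")
  for (i in seq_len(nrow(populations))) {
    par <- populations$parent[i]
    if (!is.na(par) && !par %in% populations$label[seq_len(i - 1)]) {
      stop("parent '", par, "' of '", populations$label[i],
           "' must be listed before its child")
    }
  }
  targets <- vapply(admixture_events, `[[`, character(1), "target")
  for (ev in admixture_events) {
    if (abs(sum(ev$proportions) - 1) > 1e-9) {
      stop("admixture proportions must sum to 1 for target ", ev$target)
    }
    if (length(ev$proportions) != length(ev$sources)) {
      stop("proportions/sources length mismatch for target ", ev$target)
    }
    missing_pops <- setdiff(c(ev$target, ev$sources), populations$label)
    if (length(missing_pops) > 0) {
      stop("admixture event references unknown populations: ",
           paste(missing_pops, collapse = ", "))
    }
  }
  if (anyDuplicated(targets)) {
    stop("duplicate admixture targets: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  }
  if (!is.null(signature)) {
    stopifnot(all(c("affected", "n_snps", "delta") %in% names(signature)))
    if (signature$n_snps > n_snps) stop("signature SNPs exceed n_snps")
  }
  structure(list(n_snps = as.integer(n_snps), populations = populations,
                 admixture_events = admixture_events,
                 missing_rate = missing_rate,
                 ancestral_freq_law = ancestral_freq_law,
                 signature = signature, pseudo_haploid = pseudo_haploid,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

.draw_ancestral <- function(law, m) {
  switch(law$law,
         uniform = stats::runif(m, law$min, law$max),
         beta = stats::rbeta(m, law$shape1, law$shape2),
         stop("unknown ancestral_freq_law: ", law$law))
}

.bn_drift <- function(p, fst) {
  if (fst < 1e-9) return(p)
  x <- stats::rbeta(length(p), p * (1 - fst) / fst, (1 - p) * (1 - fst) / fst)
  pmin(pmax(x, 1e-6), 1 - 1e-6)
}

#' Simulate a genotype matrix from a scenario
#'
#' @param spec a [scenario_spec()].
#' @return A `scenario_sim` list: `matrix` (a [genotype_matrix()]),
#'   `truth` (data.frame of every true admixture proportion),
#'   `pop_freqs` (population x SNP true frequencies) and `spec`. Fully
#'   reproducible given the spec's seed.
#' @export
simulate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  m <- spec$n_snps
  seed <- spec$seed
  p_anc <- with_substream(seed, "ancestral",
                          .draw_ancestral(spec$ancestral_freq_law, m))
  pops <- spec$populations
  targets <- vapply(spec$admixture_events, `[[`, character(1), "target")
  freqs <- matrix(NA_real_, nrow = nrow(pops), ncol = m,
                  dimnames = list(pops$label, NULL))
  for (i in seq_len(nrow(pops))) {
    lab <- pops$label[i]
    if (lab %in% targets) next
    base <- if (is.na(pops$parent[i])) p_anc else freqs[pops$parent[i], ]
    if (anyNA(base)) {
      stop("parent of ", lab, " is an admixture target simulated later; reorder")
    }
    freqs[lab, ] <- with_substream(seed, paste0("drift-", lab),
                                   .bn_drift(base, pops$fst[i]))
  }
  truth_rows <- list()
  for (ev in spec$admixture_events) {
    if (anyNA(freqs[ev$sources, ])) {
      stop("sources of ", ev$target, " not yet simulated; reorder events")
    }
    p_t <- drop(ev$proportions %*% freqs[ev$sources, , drop = FALSE])
    post <- if (is.null(ev$post_drift)) 0 else ev$post_drift
    if (post > 0) {
      p_t <- with_substream(seed, paste0("postdrift-", ev$target),
                            .bn_drift(p_t, post))
    }
    freqs[ev$target, ] <- p_t
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(target = ev$target, source = ev$sources,
                 alpha = ev$proportions, stringsAsFactors = FALSE)
  }
  truth <- if (length(truth_rows) > 0) do.call(rbind, truth_rows)
           else data.frame(target = character(0), source = character(0),
                           alpha = numeric(0))

  n_total <- sum(pops$n)
  calls <- matrix(NA_integer_, nrow = n_total, ncol = m)
  sample_pop <- rep(pops$label, pops$n)
  row <- 1
  for (i in seq_len(nrow(pops))) {
    if (pops$n[i] == 0) next
    lab <- pops$label[i]
    g <- with_substream(seed, paste0("geno-", lab), {
      if (spec$pseudo_haploid) {
        matrix(2L * stats::rbinom(pops$n[i] * m, 1,
                                  rep(freqs[lab, ], each = pops$n[i])),
               nrow = pops$n[i])
      } else {
        matrix(stats::rbinom(pops$n[i] * m, 2,
                             rep(freqs[lab, ], each = pops$n[i])),
               nrow = pops$n[i])
      }
    })
    calls[row:(row + pops$n[i] - 1), ] <- g
    row <- row + pops$n[i]
  }
  if (spec$missing_rate > 0) {
    mask <- with_substream(seed, "missing", {
      matrix(stats::runif(n_total * m) < spec$missing_rate, nrow = n_total)
    })
    calls[mask] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = sprintf("%s_%03d", sample_pop,
                        stats::ave(seq_len(n_total), sample_pop,
                                   FUN = seq_along)),
    population = sample_pop, stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)),
                     chromosome = "1", genetic_pos = (seq_len(m) - 1) * 1e-5,
                     physical_pos = seq_len(m) * 1000L,
                     ref_allele = "A", alt_allele = "G",
                     stringsAsFactors = FALSE)
  sim <- structure(list(matrix = genotype_matrix(calls, samples, snps),
                        truth = truth, pop_freqs = freqs, spec = spec),
                   class = "scenario_sim")
  if (!is.null(spec$signature)) {
    sim <- plant_marginal_signature(sim, spec$signature, seed)
  }
  sim
}

#' Plant a cryptic low-variance signature
#'
#' Shifts allele frequencies by `delta` at a random SNP subset for the
#' affected populations only and resamples their calls there (preserving
#' the missingness pattern). With a small subset and moderate `delta` the
#' added variance is marginal relative to the main population structure,
#' so the signature is recoverable only on a low-variance PC — the
#' situation the screening method exists for. Warns when the shifted
#' frequencies had to be clipped to `[0, 1]` or when the subset exceeds 5%
#' of SNPs (no longer "low-variance").
#'
#' @param sim a `scenario_sim` from [simulate_scenario()].
#' @param signature `list(affected =, n_snps =, delta =)`.
#' @param seed integer seed (substreamed; same seed, same output).
#' @return The modified `scenario_sim`, with `signature_snps` recording
#'   the affected SNP indices.
#' @export
plant_marginal_signature <- function(sim, signature, seed) {
  stopifnot(inherits(sim, "scenario_sim"))
  affected <- signature$affected
  missing_pops <- setdiff(affected, sim$spec$populations$label)
  if (length(missing_pops) > 0) {
    stop("unknown affected populations: ",
         paste(missing_pops, collapse = ", "))
  }
  if (signature$delta == 0) return(sim)
  m <- sim$spec$n_snps
  if (signature$n_snps > m) stop("signature SNPs exceed n_snps")
  if (signature$n_snps / m > 0.05) {
    warning("signature spans more than 5% of SNPs; no longer a marginal signal")
  }
  with_substream(seed, "signature", {
    idx <- sort(sample.int(m, signature$n_snps))
    clipped <- FALSE
    for (lab in affected) {
      p_new <- sim$pop_freqs[lab, idx] + signature$delta
      if (any(p_new < 0 | p_new > 1)) clipped <- TRUE
      p_new <- pmin(pmax(p_new, 1e-6), 1 - 1e-6)
      sim$pop_freqs[lab, idx] <- p_new
      rows <- which(sim$matrix$samples$population == lab)
      old <- sim$matrix$calls[rows, idx, drop = FALSE]
      g <- if (sim$spec$pseudo_haploid) {
        matrix(2L * stats::rbinom(length(rows) * length(idx), 1,
                                  rep(p_new, each = length(rows))),
               nrow = length(rows))
      } else {
        matrix(stats::rbinom(length(rows) * length(idx), 2,
                             rep(p_new, each = length(rows))),
               nrow = length(rows))
      }
      g[is.na(old)] <- NA_integer_
      sim$matrix$calls[rows, idx] <- g
    }
    if (clipped) warning("signature shift clipped at frequency bounds")
    sim$signature_snps <- idx
    sim
  })
}

#' Ready-made scenario specifications mirroring the study designs
#'
#' Three named scenarios capture the demographic settings the package's
#' analyses are validated on:
#' \describe{
#'   \item{`barbaricum5`}{one target admixed from five balanced source
#'     components with proportions `(0.218, 0.211, 0.205, 0.194, 0.172)`
#'     (five contributions of roughly one fifth each, normalized to
#'     sum 1).}
#'   \item{`gradient`}{five admixed populations whose Baltic-analogue
#'     proportion steps through `0, 0.25, 0.5, 0.75, 1`, producing a
#'     monotone ancestry cline between the two sources.}
#'   \item{`three_wave`}{three admixed target populations with
#'     Baltic-analogue fractions `0.55`, `0.275` and `0.375` — the
#'     midpoints of the ranges characterizing three successive migration
#'     waves (an early wave above 50%, a middle wave at 25–30%, and a
#'     late wave at 35–40%).}
#' }
#' Every scenario includes four deeply drifted outgroup populations
#' (`Outgroup1..4`, F = 0.35) to serve as the right panel of the
#' admixture fits.
#'
#' @param name one of `"barbaricum5"`, `"gradient"`, `"three_wave"`.
#' @param n_snps SNPs to simulate (default 20,000).
#' @param seed integer master seed.
#' @param missing_rate per-call missing probability.
#' @return A [scenario_spec()].
#' @export
make_paper_analogue_scenario <- function(name, n_snps = 20000, seed = 1,
                                         missing_rate = 0.3) {
  if (name == "barbaricum5") {
    src <- c("Germanic", "Balkan_IA", "Proto_Slavic", "Byzantine",
             "Steppe_Sarmatian")
    alpha <- c(21.5, 20.8, 20.2, 19.1, 16.9)
    alpha <- alpha / sum(alpha)
    pops <- rbind(
      .branched_sources(src, n = 30),
      data.frame(label = "Barbaricum", fst = 0.01, n = 30,
                 parent = NA_character_, stringsAsFactors = FALSE),
      .deep_outgroups())
    events <- list(list(target = "Barbaricum", sources = src,
                        proportions = alpha, post_drift = 0))
  } else if (name == "gradient") {
    alphas <- c(0, 0.25, 0.5, 0.75, 1)
    tlabels <- sprintf("Cline_%03.0f", 100 * alphas)
    pops <- rbind(
      .branched_sources(c("Baltic_BA", "Balkan_IA"), n = 20),
      data.frame(label = tlabels, fst = 0.01, n = 15,
                 parent = NA_character_, stringsAsFactors = FALSE),
      .deep_outgroups())
    events <- lapply(seq_along(alphas), function(i) {
      list(target = tlabels[i], sources = c("Baltic_BA", "Balkan_IA"),
           proportions = c(alphas[i], 1 - alphas[i]), post_drift = 0)
    })
  } else if (name == "three_wave") {
    waves <- c(wave1_early = 0.55, wave2_avar = 0.275, wave3_late = 0.375)
    pops <- rbind(
      .branched_sources(c("Baltic_BA", "Balkan_IA"), n = 30),
      data.frame(label = names(waves), fst = 0.01, n = 30,
                 parent = NA_character_, stringsAsFactors = FALSE),
      .deep_outgroups())
    events <- lapply(seq_along(waves), function(i) {
      list(target = names(waves)[i], sources = c("Baltic_BA", "Balkan_IA"),
           proportions = c(waves[[i]], 1 - waves[[i]]), post_drift = 0)
    })
  } else {
    stop("unknown scenario '", name,
         "'; options: barbaricum5, gradient, three_wave")
  }
  scenario_spec(n_snps = n_snps, populations = pops,
                admixture_events = events, missing_rate = missing_rate,
                seed = seed)
}

# Each source tip shares an internal branch with a same-branch reference
# population "<label>_ref": the refs make the right panel differentially
# related to the sources, which is what gives the f4 system its power.
.branched_sources <- function(labels, n, n_ref = 12, branch_fst = 0.06,
                              tip_fst = 0.03) {
  do.call(rbind, lapply(labels, function(lab) {
    data.frame(label = c(paste0(lab, "_branch"), lab, paste0(lab, "_ref")),
               fst = c(branch_fst, tip_fst, tip_fst),
               n = c(0, n, n_ref),
               parent = c(NA_character_, paste0(lab, "_branch"),
                          paste0(lab, "_branch")),
               stringsAsFactors = FALSE)
  }))
}

.deep_outgroups <- function(k = 2, fst = 0.35, n = 12) {
  data.frame(label = paste0("Outgroup", seq_len(k)), fst = fst, n = n,
             parent = NA_character_, stringsAsFactors = FALSE)
}

#' Right-panel labels of a built-in scenario
#'
#' The per-source `_ref` populations plus the deep outgroups — the panel
#' to pass as `right_pops` to the admixture fits.
#'
#' @param spec a [scenario_spec()] built by [make_paper_analogue_scenario()]
#'   or [make_admixture_scenario()].
#' @return Character vector of population labels.
#' @export
scenario_right_panel <- function(spec) {
  labs <- spec$populations$label
  c(grep("_ref$", labs, value = TRUE), grep("^Outgroup", labs, value = TRUE))
}

#' Two-source admixture scenario for parameter-recovery studies
#'
#' A target mixing two sources (`Target = alpha SourceA + (1 - alpha)
#' SourceB`), each source on its own internal branch shared with a
#' reference population, plus two deep outgroups — a four-population right
#' panel in total. Optional decoy populations (unrelated to the target's
#' ancestry: one on its own branch, one drifted straight from the
#' ancestor) support model-selection studies, and `copy_of` replaces the
#' admixed target by an (essentially) undrifted copy of one source — the
#' null case for rank tests.
#'
#' @param alpha true mixture proportion of `SourceA`.
#' @param n_snps SNPs (default 20,000).
#' @param n_per_pop samples per source/target (default 30).
#' @param n_decoys 0, 1 or 2 decoy source populations.
#' @param copy_of optional source label the target should copy.
#' @param seed integer master seed.
#' @param missing_rate per-call missing probability.
#' @return A [scenario_spec()]; right panel via [scenario_right_panel()].
#' @export
make_admixture_scenario <- function(alpha = 0.5, n_snps = 20000,
                                    n_per_pop = 30, n_decoys = 0,
                                    copy_of = NULL, seed = 1,
                                    missing_rate = 0.3) {
  pops <- rbind(.branched_sources(c("SourceA", "SourceB"), n = n_per_pop),
                .deep_outgroups())
  if (n_decoys >= 1) {
    pops <- rbind(pops, data.frame(
      label = c("DecoyC_branch", "DecoyC"), fst = c(0.06, 0.03),
      n = c(0, n_per_pop), parent = c(NA_character_, "DecoyC_branch"),
      stringsAsFactors = FALSE))
  }
  if (n_decoys >= 2) {
    pops <- rbind(pops, data.frame(
      label = "DecoyD", fst = 0.1, n = n_per_pop, parent = NA_character_,
      stringsAsFactors = FALSE))
  }
  if (is.null(copy_of)) {
    pops <- rbind(pops, data.frame(
      label = "Target", fst = 0.01, n = n_per_pop, parent = NA_character_,
      stringsAsFactors = FALSE))
    events <- list(list(target = "Target",
                        sources = c("SourceA", "SourceB"),
                        proportions = c(alpha, 1 - alpha), post_drift = 0))
  } else {
    pops <- rbind(pops, data.frame(
      label = "Target", fst = 1e-12, n = n_per_pop, parent = copy_of,
      stringsAsFactors = FALSE))
    events <- list()
  }
  scenario_spec(n_snps = n_snps, populations = pops,
                admixture_events = events, missing_rate = missing_rate,
                seed = seed)
}

#' Scenario with a planted cryptic signature on shared ancestry
#'
#' The benchmark design for the screening method: three diverged ancestry
#' clusters dominate the leading PCs, while two further groups share one
#' ancestry and differ only through a planted frequency shift of `delta`
#' at `signature_frac` of the SNPs — a signal that surfaces on a marginal
#' PC only.
#'
#' @param n_snps SNPs (default 20,000).
#' @param n_per_group samples per signature group (default 30).
#' @param delta planted frequency shift (default 0.3).
#' @param signature_frac fraction of SNPs carrying the shift (default 0.02).
#' @param seed integer master seed.
#' @param missing_rate per-call missing probability.
#' @return A [scenario_spec()] whose groups `SignalGroup` and
#'   `ShadowGroup` share ancestry apart from the planted signature.
#' @export
make_planted_signature_scenario <- function(n_snps = 20000, n_per_group = 30,
                                            delta = 0.3,
                                            signature_frac = 0.02, seed = 1,
                                            missing_rate = 0.3) {
  pops <- rbind(
    data.frame(label = c("AncestryA", "AncestryB", "AncestryC"),
               fst = 0.15, n = 40, stringsAsFactors = FALSE),
    data.frame(label = c("SignalGroup", "ShadowGroup"), fst = 0.05,
               n = n_per_group, stringsAsFactors = FALSE))
  events <- list(
    list(target = "SignalGroup", sources = c("AncestryA", "AncestryB"),
         proportions = c(0.5, 0.5), post_drift = 0.005),
    list(target = "ShadowGroup", sources = c("AncestryA", "AncestryB"),
         proportions = c(0.5, 0.5), post_drift = 0.005))
  scenario_spec(
    n_snps = n_snps, populations = pops, admixture_events = events,
    missing_rate = missing_rate,
    signature = list(affected = "SignalGroup",
                     n_snps = round(signature_frac * n_snps), delta = delta),
    seed = seed)
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("scenario_spec: %d SNPs, %d populations (%d admixture events), seed %d\n",
              x$n_snps, nrow(x$populations), length(x$admixture_events),
              x$seed))
  invisible(x)
}

#' @export
print.scenario_sim <- function(x, ...) {
  print(x$matrix)
  if (nrow(x$truth) > 0) {
    cat("truth table:\n")
    print(x$truth, row.names = FALSE)
  }
  invisible(x)
}

#' Write a simulation to EIGENSTRAT files plus a truth table
#'
#' @param sim a `scenario_sim`.
#' @param prefix output path prefix.
#' @return Invisibly, the files written.
#' @export
write_scenario <- function(sim, prefix) {
  files <- write_genotypes(sim$matrix, prefix, format = "eigenstrat")
  truth_path <- paste0(prefix, "_truth.tsv")
  utils::write.table(sim$truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(files, truth = truth_path))
}
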