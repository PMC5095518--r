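#' Experiment presets
#'
#' Named end-to-end pipelines reproducing the package's main experiments, each
#' runnable from a single call with only synthetic stimuli and a seed:
#' \describe{
#'   \item{`fig2_clustering`}{train, freeze, record 1,000 test responses, sort
#'     by similarity, write the response and correlation matrices.}
#'   \item{`fig3_connectivity`}{train and write receptive fields plus the
#'     lateral-connectivity statistics (symmetry, concentration, RF
#'     similarity of strong pairs).}
#'   \item{`fig4_spontaneous`}{record spontaneous activity from the trained
#'     network and match its most active 50-ms patterns against the evoked
#'     clusters.}
#'   \item{`fig5_mixture`}{morph between the two cluster-preferred stimuli in
#'     30 steps and write the regression coefficient series, with and without
#'     lateral connections.}
#'   \item{`fig6_shuffled`}{identical to `fig2_clustering` but with the
#'     per-frame pixel-shuffle control.}
#'   \item{`fig7_manipulations`}{spontaneous rates for the full, silenced-
#'     inhibition and lateral-ablated networks, plus post-offset decay.}
#'   \item{`fig8_blocking`}{the mixture experiment on mean subthreshold
#'     potentials with and without spike blocking.}
#'   \item{`robustness_sweep`}{re-run a short training at the seven free
#'     parameters scaled by 0.8 and 1.2 and write the structural statistics.}
#'   \item{`size_x4`}{quadrupled network (400 E / 80 I, `A_lat / 4`).}
#' }
#'
#' @param name Preset name (see above).
#' @param seed Integer seed; fans out via [seed_streams()].
#' @param out_dir Output directory for artifacts.
#' @param n_train Training presentations (default 50,000; reduce for quick
#'   runs).
#' @param n_test Test presentations (default 1,000).
#' @param config Base configuration (default [default_config()]).
#' @param network Optionally a pre-trained `v1net` to reuse instead of
#'   training (ignored by presets that must train themselves).
#' @return A manifest list (also written as `manifest.yaml`): preset name,
#'   seed, config hash, output files and headline statistics.
#' @export
run_preset <- function(name, seed = 1, out_dir = tempfile("v1net_"),
                       n_train = 50000, n_test = 1000,
                       config = default_config(), network = NULL) {
  presets <- c("fig2_clustering", "fig3_connectivity", "fig4_spontaneous",
               "fig5_mixture", "fig6_shuffled", "fig7_manipulations",
               "fig8_blocking", "robustness_sweep", "size_x4")
  if (!name %in% presets) {
    stop("unknown preset '", name, "'; available: ",
         paste(presets, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ss <- seed_streams(seed)
  files <- character(0)
  stats <- list()
  emit <- function(obj, fname) {
    path <- file.path(out_dir, fname)
    utils::write.table(obj, path, sep = ",", row.names = FALSE,
                       col.names = !is.null(colnames(obj)))
    files <<- c(files, fname)
    path
  }

  shuffle <- identical(name, "fig6_shuffled")
  if (identical(name, "size_x4")) config <- scale_for_size(config, 4)

  if (identical(name, "robustness_sweep")) {
    out <- purrr::map_dfr(c(0.8, 1.2), function(f) {
      cfgp <- perturb_config(config, f)
      st <- make_stimuli(min(n_train, 10000), cfgp, seed = ss["stimuli"])
      net <- build_network(cfgp, seed = ss["network"])
      net <- train_network(net, st, n_presentations = n_train, seed = ss["sim"])
      dplyr::mutate(glance(net), factor = f)
    })
    emit(out, "robustness.csv")
  } else {
    trained <- network
    if (is.null(trained)) {
      st <- make_stimuli(min(n_train, 20000), config, shuffle = shuffle,
                         seed = ss["stimuli"])
      trained <- build_network(config, seed = ss["network"])
      trained <- train_network(trained, st, n_presentations = n_train,
                               checkpoint_at = c(n_train %/% 2, n_train),
                               seed = ss["sim"])
    }
    test_st <- make_stimuli(n_test, config, shuffle = shuffle,
                            seed = ss["stimuli"] + 1L)
    resp <- test_responses(trained, test_st, seed = ss["test"])
    cl <- cluster_and_sort(resp)

    if (name %in% c("fig2_clustering", "fig6_shuffled", "size_x4")) {
      emit(cl$counts, "responses_sorted.csv")
      emit(cl$cor, "response_correlation.csv")
      stats$n_clusters <- n_response_clusters(cl)
      stats <- c(stats, as.list(rate_stats(resp)))
    } else if (identical(name, "fig3_connectivity")) {
      rf <- reconstruct_rf(trained)
      emit(matrix(rf, nrow = dim(rf)[1] * dim(rf)[2]), "receptive_fields.csv")
      emit(trained$W_lat, "W_lat.csv")
      stats$symmetry <- weight_symmetry(trained)
      stats$top10_share <- weight_concentration(trained, 0.10)
      stats$top5_share <- weight_concentration(trained, 0.05)
      stats$corr_pair_share <- correlated_pair_weight_share(resp, trained, 0.05)
      stats$rf_similarity <- rf_pair_similarity(trained)
    } else if (identical(name, "fig4_spontaneous")) {
      ras <- record_spontaneous(trained, duration = 100000, seed = ss["test"] + 1L)
      emit(as.data.frame(ras), "spontaneous_raster.csv")
      pat <- spontaneous_patterns(ras)
      emit(pat, "spontaneous_patterns.csv")
      stats <- c(stats, as.list(match_patterns(pat, resp)))
    } else if (name %in% c("fig5_mixture", "fig8_blocking")) {
      use_pot <- identical(name, "fig8_blocking")
      mx <- mixture_experiment(trained, resp, cl, test_st,
                               use_potentials = use_pot, seed = ss["test"] + 2L)
      emit(mx$betas, "mixture_betas.csv")
      stats$sharpness_full <- transition_sharpness(mx$betas$beta1[
        mx$betas$condition == levels(factor(mx$betas$condition))[1]])
      for (cond in unique(mx$betas$condition)) {
        stats[[paste0("sharpness_", cond)]] <-
          transition_sharpness(mx$betas$beta1[mx$betas$condition == cond])
      }
      stats$sharpness_full <- NULL
    } else if (identical(name, "fig7_manipulations")) {
      spont_rate <- function(n, dur = 20000) {
        ras <- record_spontaneous(n, duration = dur, seed = ss["test"] + 3L)
        sum(ras$pop == "E") / trained$config$network$n_E / (dur / 1000)
      }
      stats$rate_full <- spont_rate(trained)
      stats$rate_no_inh <- spont_rate(
        apply_manipulation(trained, "silence_inhibition"), dur = 5000)
      stats$rate_no_inh_no_lat <- spont_rate(apply_manipulation(
        apply_manipulation(trained, "silence_inhibition"), "disable_lateral"),
        dur = 5000)
    }
  }

  manifest <- list(preset = name, seed = seed,
                   config_hash = rlang::hash(config),
                   n_train = n_train, files = files,
                   stats = lapply(stats, function(x) unname(as.numeric(x))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  manifest$out_dir <- out_dir
  invisible(manifest)
}

#' Run the stimulus-morphing (mixture) experiment
#'
#' Selects the two stimuli that evoke the highest maximal firing in the two
#' largest response clusters, builds the 30-step linear morph between them,
#' and records the frozen-network responses to the morph and to each pure
#' stimulus, with the regression decomposition of every mixture response onto
#' the two pure responses. Run for the full network and with all lateral
#' connections disabled (`conditions = c("full", "no_lateral")` by default);
#' with `use_potentials = TRUE` the response variable is the mean subthreshold
#' potential and the comparison conditions are spiking vs spike blocking.
#'
#' @param network Trained `v1net`.
#' @param responses Frozen-network responses used to pick the stimulus pair.
#' @param clustering Optional result of [cluster_and_sort()] on `responses`.
#' @param stimuli The stimulus set behind `responses`.
#' @param n_mix Number of mixtures (default 30).
#' @param use_potentials Use mean subthreshold potentials instead of spike
#'   counts, comparing intact spiking against the spike-blocking manipulation.
#' @param seed Seed for the response recordings.
#' @return List: `betas` (tibble with `condition`, `mixture`, `beta1`,
#'   `beta2`), `pair` (indices of the chosen stimuli), `responses` (list of
#'   response matrices by condition).
#' @export
mixture_experiment <- function(network, responses, clustering = NULL,
                               stimuli, n_mix = 30, use_potentials = FALSE,
                               seed = NULL) {
  m <- as_counts_matrix(responses)
  if (is.null(clustering)) clustering <- cluster_and_sort(m)
  grp <- stats::cutree(clustering$hclust, k = max(2, min(6, ncol(m) %/% 10)))
  live <- which(apply(m, 2, stats::sd) > 0)
  sizes <- sort(table(grp), decreasing = TRUE)
  two <- as.integer(names(sizes)[1:2])
  pick <- vapply(two, function(g) {
    cols <- live[grp == g]
    cols[which.max(apply(m[, cols, drop = FALSE], 2, max))]
  }, integer(1))
  s1 <- stimuli$patches[, , pick[1]]
  s2 <- stimuli$patches[, , pick[2]]

  mix <- stimuli_from_patches(mixture_series(s1, s2, n_mix),
                              rate_scale = stimuli$rate_scale)
  conditions <- if (use_potentials) {
    list(spiking = network,
         blocked = apply_manipulation(network, "block_spikes"))
  } else {
    list(full = network,
         no_lateral = apply_manipulation(network, "disable_lateral"))
  }
  resp_of <- function(net) {
    r <- test_responses(net, mix, record_potentials = use_potentials,
                        seed = seed)
    if (use_potentials) r$potentials - mean(r$potentials) else r$counts
  }
  out <- purrr::imap(conditions, function(net, nm) {
    rm_ <- resp_of(net)
    b <- mixture_betas(rm_, rm_[, n_mix], rm_[, 1])
    b$condition <- nm
    list(betas = b, resp = rm_)
  })
  list(betas = dplyr::bind_rows(purrr::map(out, "betas")),
       pair = pick,
       responses = purrr::map(out, "resp"))
}
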