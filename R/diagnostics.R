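# Homolog-variant screening from heterozygote allele-depth balance, and
# ploidy inference from per-individual allele-ratio distributions.

#' Homolog allele-depth Z-score per variant
#'
#' At a genuine allelic variant, reads over heterozygous individuals support
#' the two alleles in a 1:1 ratio; apparent variants created by collapsed
#' homologous loci (paralogs, homoeologs) show a systematic imbalance. The
#' deviation of the heterozygote allele-depth ratio from 1:1 is expressed as
#' a Z-score under a binomial model with success probability 0.5.
#'
#' With pooled reference depth `x` and pooled total depth `n` over all
#' heterozygous individuals (the default `method = "pooled"`),
#' `z = (x - n/2) / sqrt(n/4)`. `method = "mean"` instead averages the
#' per-individual reference-allele ratios and standardizes the mean by the
#' delta-method variance `sum(1/(4 n_i)) / m^2`. Variants with no
#' heterozygotes are flagged not evaluable and are never culled.
#'
#' @param calls a `gbs_calls` object (per-individual `AD` fields required).
#' @param method `"pooled"` (default) or `"mean"`.
#' @return `data.table` with one row per variant: `variant_id`, `n_het`,
#'   `x` (pooled ref depth over hets), `n` (pooled total), `ratio`, `z`,
#'   `evaluable`.
#' @export
homolog_z <- function(calls, method = c("pooled", "mean")) {
  method <- match.arg(method)
  g <- calls$genotypes
  if (any(g$ad_ref < 0 | g$ad_alt < 0, na.rm = TRUE))
    stop("negative allele depths", call. = FALSE)
  hets <- g[gt == "het" & (ad_ref + ad_alt) > 0]
  st <- hets[, .(n_het = .N, x = sum(ad_ref), n = sum(ad_ref + ad_alt),
                 mean_ratio = mean(ad_ref / (ad_ref + ad_alt)),
                 se_mean = sqrt(sum(1 / (4 * (ad_ref + ad_alt)))) / .N),
             by = variant_id]
  if (method == "pooled") {
    st[, ratio := x / n]
    st[, z := (x - n / 2) / sqrt(n / 4)]
  } else {
    st[, ratio := mean_ratio]
    st[, z := (mean_ratio - 0.5) / se_mean]
  }
  st[, se_mean := NULL][, mean_ratio := NULL]
  out <- merge(data.table(variant_id = calls$calls$variant_id), st,
               by = "variant_id", all.x = TRUE, sort = FALSE)
  out[is.na(n_het), `:=`(n_het = 0L, x = 0L, n = 0L)]
  out[, evaluable := n_het > 0 & n > 0]
  out[evaluable == FALSE, `:=`(ratio = NA_real_, z = NA_real_)]
  out[]
}

#' Filter likely homolog variants
#'
#' Computes (or reuses) [homolog_z()] statistics, fills the `zscore` column
#' of the calls, and splits the set at `|z| > z_threshold` (strict
#' inequality; the conventional conservative threshold is 5). Variants with
#' no heterozygotes carry no evidence either way and are always retained.
#'
#' @param calls a `gbs_calls` object.
#' @param z_threshold positive cull threshold on `|z|`.
#' @param method passed to [homolog_z()].
#' @return list with `retained` and `culled` (`gbs_calls` objects, `zscore`
#'   filled) and `stats` (the [homolog_z()] table plus a `culled` flag).
#' @export
filter_homologs <- function(calls, z_threshold = 5, method = c("pooled", "mean")) {
  st <- homolog_z(calls, method)
  st[, culled := evaluable & abs(z) > z_threshold]
  calls$calls[, zscore := st$z[match(variant_id, st$variant_id)]]
  keep <- st[culled == FALSE]$variant_id
  drop <- st[culled == TRUE]$variant_id
  list(retained = subset_calls(calls, keep),
       culled = subset_calls(calls, drop),
       stats = st[])
}

#' Write homolog statistics
#'
#' @param stats the `stats` table from [filter_homologs()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_homolog_stats <- function(stats, path) {
  fwrite(stats, path, sep = "\t")
  invisible(path)
}

#' Allele-depth ratios at an individual's heterozygous calls
#'
#' @param calls a `gbs_calls` object.
#' @param individual_id one individual.
#' @param min_depth minimum `ad_ref + ad_alt` for a site to contribute.
#' @return numeric vector of `alt / (ref + alt)` ratios.
#' @export
allele_ratio_distribution <- function(calls, individual_id, min_depth = 10L) {
  id <- individual_id
  g <- calls$genotypes[individual_id == id & gt == "het" &
                         (ad_ref + ad_alt) >= min_depth]
  if (nrow(g) == 0) return(numeric(0))
  g$ad_alt / (g$ad_ref + g$ad_alt)
}

# EM fit of a fixed-mean Gaussian mixture with free weights and component
# variances m_j (1 - m_j) / d tied through one free effective depth d --
# the Gaussian approximation of binomial allele-depth sampling noise, whose
# variance depends on the component mean. Returns log-likelihood, weights
# and the fitted effective depth.
fit_fixed_mixture <- function(x, means, max_iter = 200L, tol = 1e-8) {
  k <- length(means)
  n <- length(x)
  cj <- means * (1 - means)
  w <- rep(1 / k, k)
  d <- mean(cj) / max(stats::var(x), 1e-6)
  ll <- -Inf
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k), function(j)
      w[j] * dnorm(x, means[j], sqrt(cj[j] / d)), numeric(n))
    dens <- matrix(dens, nrow = n)
    rowsum_ <- pmax(rowSums(dens), 1e-300)
    ll <- sum(log(rowsum_))
    resp <- dens / rowsum_
    w <- colMeans(resp)
    d <- n / sum(resp * sweep(outer(x, means, "-")^2, 2, cj, "/"))
    d <- min(max(d, 1), 1e4)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(loglik = ll, weights = w, d_eff = d)
}

#' Infer ploidy from an allele-ratio distribution
#'
#' Scores three fixed-mean Gaussian mixture models for the distribution of
#' heterozygote allele-depth ratios: diploid (mean 1/2), triploid (means
#' 1/3, 2/3) and tetraploid (means 1/4, 1/2, 3/4). Each model has free
#' mixture weights; component variances are tied as `m (1 - m) / d` through
#' a single free effective depth `d`, mirroring binomial allele-sampling
#' noise whose spread depends on the allele-balance mean. Parameters are
#' fitted by expectation-maximization. Because the richer models nest the
#' simpler ones, the reported `best_model` is chosen by BIC; the full
#' log-likelihood table is returned so other criteria can be applied.
#'
#' @param ratios numeric vector of allele-depth ratios in (0, 1).
#' @param min_sites minimum number of ratios; below it the report carries
#'   status `insufficient data` and no `best_model`.
#' @param max_iter,tol EM controls.
#' @return object of class `ploidy_report`: `n_sites`, `status`, `models`
#'   (`data.table`: `model`, `k`, `loglik`, `bic`, `weights`), `best_model`
#'   (`NA` when insufficient), `histogram` (20 equal bins over `[0, 1]`).
#' @export
infer_ploidy <- function(ratios, min_sites = 30L, max_iter = 200L, tol = 1e-8) {
  ratios <- ratios[is.finite(ratios) & ratios > 0 & ratios < 1]
  breaks <- seq(0, 1, length.out = 21L)
  histo <- table(cut(ratios, breaks, include.lowest = TRUE))
  if (length(ratios) < min_sites) {
    return(structure(list(n_sites = length(ratios),
                          status = "insufficient data",
                          models = NULL, best_model = NA_character_,
                          histogram = histo),
                     class = "ploidy_report"))
  }
  model_means <- list(diploid = 1 / 2, triploid = c(1 / 3, 2 / 3),
                      tetraploid = c(1 / 4, 1 / 2, 3 / 4))
  n <- length(ratios)
  rows <- lapply(names(model_means), function(m) {
    fit <- fit_fixed_mixture(ratios, model_means[[m]], max_iter, tol)
    npar <- length(model_means[[m]]) - 1L + 1L # free weights + effective depth
    data.table(model = m, k = length(model_means[[m]]), loglik = fit$loglik,
               bic = -2 * fit$loglik + npar * log(n),
               weights = paste(formatC(fit$weights, format = "f", digits = 3),
                               collapse = ","),
               d_eff = fit$d_eff)
  })
  models <- rbindlist(rows)
  structure(list(n_sites = n, status = "ok", models = models,
                 best_model = models$model[which.min(models$bic)],
                 histogram = histo),
            class = "ploidy_report")
}

#' @export
print.ploidy_report <- function(x, ...) {
  if (x$status != "ok") {
    cat(sprintf("ploidy: %s (%d ratios)\n", x$status, x$n_sites))
    return(invisible(x))
  }
  cat(sprintf("ploidy: best model %s over %d het-site ratios\n",
              x$best_model, x$n_sites))
  print(x$models[, .(model, loglik, bic)])
  invisible(x)
}

#' Per-individual ploidy reports
#'
#' Runs [allele_ratio_distribution()] and [infer_ploidy()] for every
#' individual.
#'
#' @param calls a `gbs_calls` object.
#' @param min_depth minimum site depth for a ratio to contribute.
#' @param ... passed to [infer_ploidy()].
#' @return list with `summary` (`data.table`: `individual_id`,
#'   `n_het_sites`, `best_model`, per-model log-likelihoods) and `reports`
#'   (named list of `ploidy_report`s).
#' @export
infer_ploidy_all <- function(calls, min_depth = 10L, ...) {
  reports <- lapply(calls$individuals, function(i)
    infer_ploidy(allele_ratio_distribution(calls, i, min_depth), ...))
  names(reports) <- calls$individuals
  summary <- rbindlist(lapply(calls$individuals, function(i) {
    r <- reports[[i]]
    ll <- if (is.null(r$models)) rep(NA_real_, 3) else r$models$loglik
    data.table(individual_id = i, n_het_sites = r$n_sites,
               best_model = r$best_model, ll_diploid = ll[1],
               ll_triploid = ll[2], ll_tetraploid = ll[3])
  }))
  list(summary = summary, reports = reports)
}
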