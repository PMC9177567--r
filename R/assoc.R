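#' Apply the cohort occurrence filters
#'
#' Three rules, in order: (1) species kept when present (abundance > 0) in at
#' least `species_min_occ` of samples; (2) SV (KO) columns of retained
#' species kept when both genotype groups each hold at least `sv_group_min`
#' of that species' present samples (the denominator is present samples,
#' where genotype is defined); (3) metabolites kept when non-missing in more
#' than `metabolite_min_presence` of samples. Every dropped feature is named
#' in the filter log together with the rule.
#'
#' @param bundle a `cohort_bundle` from [simulate_cohort()] (or a list with
#'   the same matrices).
#' @param species_min_occ minimum species occurrence fraction (default 0.5).
#' @param sv_group_min minimum per-genotype group fraction (default 0.2).
#' @param metabolite_min_presence minimum metabolite presence fraction,
#'   strict (default 0.9).
#' @return a `filtered_cohort`: the bundle restricted to retained features,
#'   plus `filter_log` (data.frame feature, type, rule, kept).
#' @export
filter_cohort <- function(bundle, species_min_occ = 0.5, sv_group_min = 0.2,
                          metabolite_min_presence = 0.9) {
  ab <- bundle$abundance
  occ <- colMeans(ab > 0)
  keep_sp <- occ >= species_min_occ
  log <- data.frame(feature = colnames(ab), type = "species",
                    rule = sprintf("occurrence %.2f (min %.2f)", occ,
                                   species_min_occ),
                    kept = keep_sp, stringsAsFactors = FALSE)
  if (!any(keep_sp)) stop("no species passes the occurrence filter")

  sv <- bundle$sv_genotype
  sv_species <- sub("\\|.*$", "", colnames(sv))
  keep_sv <- logical(ncol(sv))
  rule_sv <- character(ncol(sv))
  for (j in seq_len(ncol(sv))) {
    if (!keep_sp[sv_species[j]]) {
      rule_sv[j] <- "species dropped"
      next
    }
    g <- sv[!is.na(sv[, j]), j]
    f1 <- mean(g == 1)
    keep_sv[j] <- min(f1, 1 - f1) >= sv_group_min
    rule_sv[j] <- sprintf("group fractions %.2f/%.2f (min %.2f)",
                          1 - f1, f1, sv_group_min)
  }
  log <- rbind(log, data.frame(feature = colnames(sv), type = "sv",
                               rule = rule_sv, kept = keep_sv,
                               stringsAsFactors = FALSE))

  met <- bundle$metabolites
  pres <- colMeans(!is.na(met))
  keep_met <- pres > metabolite_min_presence
  log <- rbind(log, data.frame(feature = colnames(met), type = "metabolite",
                               rule = sprintf("presence %.2f (min > %.2f)",
                                              pres, metabolite_min_presence),
                               kept = keep_met, stringsAsFactors = FALSE))

  structure(list(abundance = ab[, keep_sp, drop = FALSE],
                 sv_genotype = sv[, keep_sv, drop = FALSE],
                 metabolites = met[, keep_met, drop = FALSE],
                 phenotype = bundle$phenotype,
                 covariates = bundle$covariates,
                 truth = bundle$truth,
                 filter_log = log),
            class = "filtered_cohort")
}

#' Spearman correlation with midranks
#'
#' Exact permutation p-value for n <= 9 without ties, otherwise the
#' t-distribution approximation t = rho sqrt((n-2)/(1-rho^2)). Missing
#' values are dropped pairwise.
#'
#' @param x,y numeric vectors.
#' @return list(rho, p, n); rho is NA with a warning when either vector has
#'   zero variance.
#' @export
spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; Spearman rho undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n))
  }
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = (n <= 9L && !ties)))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals p-values in [0, 1].
#' @return BH-adjusted q-values (monotone, capped at 1).
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Screen species-target pairs by Spearman correlation with BH FDR
#'
#' For every (species, target) pair, Spearman correlation over samples where
#' the species is present (abundance > 0) and the target is observed; BH
#' adjustment across all tested pairs within the target block; significant
#' when q < `fdr`.
#'
#' @param filtered a `filtered_cohort`.
#' @param targets `"metabolites"` or `"phenotype"`.
#' @param fdr BH significance threshold (default 0.1).
#' @return data.frame of association records (species, target, ko = NA,
#'   n_all, rho_all, p_all, q_all, significant, verdict = "screen_only").
#' @export
screen_pairs <- function(filtered, targets = c("metabolites", "phenotype"),
                         fdr = 0.1) {
  targets <- match.arg(targets)
  tb <- if (targets == "metabolites") filtered$metabolites
        else matrix(filtered$phenotype, ncol = 1,
                    dimnames = list(names(filtered$phenotype), "phenotype"))
  recs <- NULL
  for (sp in colnames(filtered$abundance)) {
    pres <- filtered$abundance[, sp] > 0
    for (tg in colnames(tb)) {
      ok <- pres & !is.na(tb[, tg])
      if (sum(ok) < 3L) next
      s <- suppressWarnings(spearman(filtered$abundance[ok, sp], tb[ok, tg]))
      recs <- rbind(recs, data.frame(species = sp, target = tg,
                                     ko = NA_character_, n_all = s$n,
                                     rho_all = s$rho, p_all = s$p,
                                     stringsAsFactors = FALSE))
    }
  }
  if (is.null(recs)) stop("no testable (species, target) pair")
  recs <- recs[!is.na(recs$p_all), , drop = FALSE]
  recs$q_all <- bh_adjust(recs$p_all)
  recs$significant <- recs$q_all < fdr
  recs$verdict <- "screen_only"
  rownames(recs) <- NULL
  recs
}

#' Dissect screened associations by SV genotype (SV0 vs SV1)
#'
#' For every screen-significant (species, target) pair and every retained SV
#' (KO) column of that species, present samples are split by genotype and
#' the Spearman correlation is recomputed per subgroup. The verdict is
#' `confounded` when the all-sample screen passed (q < `fdr`), the SV-free
#' subgroup stays significant (p_sv0 < `alpha_keep`) and the SV-carrying
#' subgroup loses significance (p_sv1 > `alpha_abolish`); subgroup p-values
#' are reported raw, not re-adjusted. All tested KOs are reported.
#'
#' @param filtered a `filtered_cohort`.
#' @param screen records from [screen_pairs()].
#' @param fdr screen FDR threshold used in the verdict (default 0.1).
#' @param alpha_keep,alpha_abolish subgroup thresholds (defaults 0.05).
#' @return data.frame of association records with subgroup columns (n_sv0,
#'   rho_sv0, p_sv0, n_sv1, rho_sv1, p_sv1) and verdict in
#'   {"confounded", "not_confounded"}.
#' @export
dissect_by_sv <- function(filtered, screen, fdr = 0.1, alpha_keep = 0.05,
                          alpha_abolish = 0.05) {
  sig <- screen[screen$significant, , drop = FALSE]
  sv_species <- sub("\\|.*$", "", colnames(filtered$sv_genotype))
  out <- NULL
  for (i in seq_len(nrow(sig))) {
    sp <- sig$species[i]; tg <- sig$target[i]
    tb <- if (tg == "phenotype") filtered$phenotype
          else filtered$metabolites[, tg]
    cols <- which(sv_species == sp)
    for (j in cols) {
      g <- filtered$sv_genotype[, j]
      sub_res <- lapply(c(0, 1), function(gv) {
        ok <- !is.na(g) & g == gv & filtered$abundance[, sp] > 0 & !is.na(tb)
        if (sum(ok) < 3L) return(list(rho = NA_real_, p = NA_real_, n = sum(ok)))
        suppressWarnings(spearman(filtered$abundance[ok, sp], tb[ok]))
      })
      degenerate <- is.na(sub_res[[1]]$p) || is.na(sub_res[[2]]$p)
      confounded <- !degenerate && sig$q_all[i] < fdr &&
        sub_res[[1]]$p < alpha_keep && sub_res[[2]]$p > alpha_abolish
      out <- rbind(out, data.frame(
        species = sp, target = tg,
        ko = sub("^.*\\|", "", colnames(filtered$sv_genotype)[j]),
        n_all = sig$n_all[i], rho_all = sig$rho_all[i], p_all = sig$p_all[i],
        q_all = sig$q_all[i],
        n_sv0 = sub_res[[1]]$n, rho_sv0 = sub_res[[1]]$rho, p_sv0 = sub_res[[1]]$p,
        n_sv1 = sub_res[[2]]$n, rho_sv1 = sub_res[[2]]$rho, p_sv1 = sub_res[[2]]$p,
        verdict = if (confounded) "confounded" else "not_confounded",
        reason = if (degenerate) "subgroup n < 3" else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame())
  rownames(out) <- NULL
  out
}

#' Partial Spearman correlation controlling for covariates
#'
#' Both variables are midrank-transformed, residualised on the covariates
#' (with intercept) by least squares, and the Pearson correlation of the
#' residuals is tested with t on n - c - 2 degrees of freedom, c being the
#' number of retained (non-constant, non-collinear) covariate columns.
#'
#' @param x,y numeric vectors.
#' @param covariates sample x c matrix or data.frame (e.g. age/sex/BMI).
#' @return list(rho, p, n, df).
#' @export
partial_spearman <- function(x, y, covariates) {
  z <- as.matrix(covariates)
  ok <- !is.na(x) & !is.na(y) & stats::complete.cases(z)
  x <- x[ok]; y <- y[ok]; z <- z[ok, , drop = FALSE]
  n <- length(x)
  design <- cbind(`(Intercept)` = 1, z)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    warning("collinear covariate column(s) dropped")
    design <- design[, qrd$pivot[seq_len(qrd$rank)], drop = FALSE]
  }
  c_used <- ncol(design) - 1L
  if (n < c_used + 3L) stop("need n >= number of covariates + 3")
  rx <- rank(x); ry <- rank(y)
  res_x <- stats::lm.fit(design, rx)$residuals
  res_y <- stats::lm.fit(design, ry)$residuals
  rho <- stats::cor(res_x, res_y)
  df <- n - c_used - 2L
  tstat <- rho * sqrt(df / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(tstat), df), n = n, df = df)
}

#' Run the full SV-stratified association cascade
#'
#' Filters the cohort, screens species-target pairs, and dissects every
#' significant pair by SV genotype.
#'
#' @param bundle a `cohort_bundle`.
#' @param targets `"metabolites"` or `"phenotype"`.
#' @param fdr,alpha_keep,alpha_abolish thresholds (defaults 0.1, 0.05, 0.05).
#' @param ... filter thresholds passed to [filter_cohort()].
#' @return list(filtered, screen, dissection).
#' @export
association_cascade <- function(bundle, targets = "metabolites", fdr = 0.1,
                                alpha_keep = 0.05, alpha_abolish = 0.05, ...) {
  filtered <- filter_cohort(bundle, ...)
  screen <- screen_pairs(filtered, targets = targets, fdr = fdr)
  dissection <- dissect_by_sv(filtered, screen, fdr = fdr,
                              alpha_keep = alpha_keep,
                              alpha_abolish = alpha_abolish)
  list(filtered = filtered, screen = screen, dissection = dissection)
}
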