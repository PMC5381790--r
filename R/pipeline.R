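#' Run the full arch-shape and dentition analysis
#'
#' Orchestrates every stage of the analysis on a configuration set plus
#' formula records, in the order the study design dictates:
#' formula frequency/diversity tables; per-side GPA with semi-landmark
#' sliding and tangent projection; the measurement-error Procrustes ANOVA
#' (individual x digitising session, per side); group-level RDA and
#' phenotypic trajectory comparison per side; site x formula variance
#' partitioning per side; the matching-symmetry DA/FA decomposition per
#' analysis group; and per-landmark asymmetry tests. All tables are written
#' as tidy CSVs together with a run log (seed and settings) and a
#' plain-text summary.
#'
#' Grouping for the asymmetry stage follows the study design: one analysis
#' per (biotype, formula-class) group with enough individuals. The RDA /
#' trajectory grouping is biotype when several biotypes are present,
#' otherwise the dental-formula class.
#'
#' @param set a [configuration_set()] with both sides and >= 2 sessions.
#' @param records per-individual formula records (data frame with
#'   `individual, site, lineage, biotype, formula`); `NULL` uses the set's
#'   metadata.
#' @param outdir output directory (created if needed).
#' @param n_perm permutations for every test (>= 99).
#' @param seed integer seed; a run is fully reproducible from (input, seed).
#' @param alpha significance level for flags.
#' @param slide slide semi-landmarks?
#' @param min_group smallest group size analysed for asymmetry.
#' @return Invisibly, a `report_bundle`: list of all result tables plus the
#'   paths written.
#' @export
run_full_analysis <- function(set, records = NULL, outdir, n_perm = 999L,
                              seed = 1L, alpha = 0.05, slide = TRUE,
                              min_group = 5L) {
  stopifnot(inherits(set, "configuration_set"))
  if (n_perm < 99L) stop("n_perm must be >= 99")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  bundle <- list()
  on_fail <- function(e) stop("stage '", stage, "' failed: ",
                              conditionMessage(e), call. = FALSE)
  tryCatch({
    if (is.null(records)) {
      m <- unique(set$meta[c("individual", "site", "lineage", "biotype",
                             "dental_formula")])
      names(m)[names(m) == "dental_formula"] <- "formula"
      records <- m
    }
    stage <- "dental"
    freq <- frequency_table(records, by = c("biotype", "site"))
    div <- do.call(rbind, lapply(split(records, records$biotype), function(r) {
      tab <- table(r$formula)
      data.frame(biotype = r$biotype[1], n = sum(tab),
                 n_formulae = length(tab),
                 simpson_D = simpson_diversity(as.numeric(tab)))
    }))
    bundle$formula_frequencies <- freq
    bundle$formula_diversity <- div

    stage <- "superimposition"
    per_side <- lapply(c(L = "L", R = "R"), function(s) {
      sub <- subset_configs(set, set$meta$side == s)
      al <- gpa(sub)
      if (slide && length(set$scheme$chains)) al <- slide_semilandmarks(al)
      project_to_tangent(al)
    })

    stage <- "measurement_error"
    me_tabs <- lapply(names(per_side), function(s) {
      al <- per_side[[s]]
      aov <- procrustes_anova(al$tangent, individual = al$meta$individual,
                              side = NULL, replicate = al$meta$session,
                              n_perm = n_perm, seed = seed)
      cbind(side = s, as.data.frame(aov))
    })
    bundle$measurement_error_anova <- do.call(rbind, me_tabs)

    stage <- "group_rda"
    grouping_of <- function(al) {
      g <- al$meta$biotype
      if (length(unique(g[!is.na(g)])) < 2L) g <- al$meta$dental_formula
      factor(g)
    }
    rda_tabs <- traj_tabs <- list()
    for (s in names(per_side)) {
      al <- per_side[[s]]
      # session-averaged shape per individual
      ind <- factor(al$meta$individual)
      Ym <- rowsum(al$tangent, ind) / as.vector(table(ind))
      g_by_ind <- tapply(as.character(grouping_of(al)), ind, `[`, 1)
      grp <- factor(g_by_ind[rownames(Ym)])
      r <- rda(Ym, grp, n_perm = n_perm, seed = seed)
      rda_tabs[[s]] <- data.frame(side = s, constraint = "group",
                                  R2 = r$R2, R2_adj = r$R2_adj, P = r$P,
                                  n = r$n, n_perm = n_perm, seed = seed)
      if (nlevels(droplevels(grp)) >= 2L && all(table(grp) >= 2L)) {
        tr <- trajectory_analysis(Ym, grp, n_perm = n_perm, seed = seed,
                                  alpha = alpha)
        traj_tabs[[s]] <- cbind(side = s, tr$pairs)
      }
    }
    bundle$group_rda <- do.call(rbind, rda_tabs)
    bundle$trajectory <- if (length(traj_tabs)) do.call(rbind, traj_tabs) else
      data.frame(side = character(0))

    stage <- "variance_partition"
    vp_tabs <- list()
    for (s in names(per_side)) {
      al <- per_side[[s]]
      ind <- factor(al$meta$individual)
      Ym <- rowsum(al$tangent, ind) / as.vector(table(ind))
      site_i <- factor(tapply(as.character(al$meta$site), ind, `[`, 1)[rownames(Ym)])
      form_i <- factor(tapply(as.character(al$meta$dental_formula), ind, `[`,
                              1)[rownames(Ym)])
      if (nlevels(droplevels(site_i)) >= 2L && nlevels(droplevels(form_i)) >= 2L) {
        vp <- variance_partition(Ym, site_i, form_i, n_perm = n_perm, seed = seed)
        vp_tabs[[s]] <- cbind(side = s, as.data.frame(vp))
      }
    }
    bundle$variance_partition <- if (length(vp_tabs)) do.call(rbind, vp_tabs) else
      data.frame(side = character(0))

    stage <- "asymmetry"
    grp_key <- interaction(set$meta$biotype, set$meta$dental_formula, drop = TRUE)
    asym_tabs <- lm_tabs <- list()
    for (g in levels(grp_key)) {
      idx <- grp_key == g
      inds <- unique(set$meta$individual[idx])
      if (length(inds) < min_group) next
      sub <- subset_configs(set, set$meta$individual %in% inds)
      al <- matching_alignment(sub, slide = slide)
      dec <- decompose_asymmetry(al, n_perm = n_perm, seed = seed, alpha = alpha)
      asym_tabs[[g]] <- cbind(group = g, as.data.frame(dec$anova))
      n_sites <- length(unique(sub$meta$site))
      lm_res <- withCallingHandlers(
        per_landmark_asymmetry(al, n_perm = n_perm, seed = seed),
        warning = function(w) invokeRestart("muffleWarning"))
      lm_tabs[[g]] <- cbind(group = g, lm_res)
    }
    bundle$asymmetry_anova <- do.call(rbind, asym_tabs)
    bundle$per_landmark_asymmetry <- do.call(rbind, lm_tabs)
  }, error = on_fail)

  stage <- "write"
  tryCatch({
    paths <- character(0)
    for (nm in names(bundle)) {
      f <- file.path(outdir, paste0(nm, ".csv"))
      utils::write.csv(bundle[[nm]], f, row.names = FALSE)
      paths <- c(paths, f)
    }
    log_f <- file.path(outdir, "run_log.txt")
    writeLines(c(sprintf("archasym run %s", format(Sys.time())),
                 sprintf("configurations: %d", n_configs(set)),
                 sprintf("n_perm: %d  seed: %d  alpha: %g  slide: %s",
                         n_perm, seed, alpha, slide)), log_f)
    bundle_obj <- structure(list(tables = bundle, paths = paths,
                                 outdir = outdir, seed = seed,
                                 n_perm = n_perm, alpha = alpha),
                            class = "report_bundle")
    summary_f <- file.path(outdir, "summary.txt")
    writeLines(report(bundle_obj), summary_f)
    invisible(bundle_obj)
  }, error = on_fail)
}

#' Human-readable summary of an analysis bundle
#'
#' One section per analysis, in the order the stages ran, numbers rounded to
#' 4 decimals. A missing table is an error.
#'
#' @param bundle a `report_bundle` from [run_full_analysis()].
#' @return character vector of report lines.
#' @export
report <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  need <- c("formula_frequencies", "formula_diversity",
            "measurement_error_anova", "group_rda", "trajectory",
            "variance_partition", "asymmetry_anova", "per_landmark_asymmetry")
  miss <- setdiff(need, names(bundle$tables))
  if (length(miss)) stop("bundle lacks table(s): ", paste(miss, collapse = ", "))
  fmt_tab <- function(d) {
    d <- as.data.frame(d)
    num <- vapply(d, is.numeric, logical(1))
    d[num] <- lapply(d[num], round, 4)
    utils::capture.output(print(d, row.names = FALSE))
  }
  out <- c("=== Dental formula frequencies ===", fmt_tab(bundle$tables$formula_frequencies),
           "", "=== Formula diversity (Simpson D) ===", fmt_tab(bundle$tables$formula_diversity),
           "", "=== Measurement-error Procrustes ANOVA ===",
           fmt_tab(bundle$tables$measurement_error_anova),
           "", "=== Group RDA on shape ===", fmt_tab(bundle$tables$group_rda),
           "", "=== Trajectory comparison ===", fmt_tab(bundle$tables$trajectory),
           "", "=== Site x formula variance partition ===",
           fmt_tab(bundle$tables$variance_partition),
           "", "=== Matching-symmetry Procrustes ANOVA (DA / FA) ===",
           fmt_tab(bundle$tables$asymmetry_anova))
  asym <- bundle$tables$asymmetry_anova
  for (g in unique(asym$group)) {
    rows <- asym[asym$group == g, ]
    da_p <- rows$P[rows$effect == "Side"]
    fa_p <- rows$P[rows$effect == "Individual × Side"]
    out <- c(out, sprintf("group %s: DA %s (P = %s), FA %s (P = %s)", g,
                          ifelse(isTRUE(da_p < bundle$alpha), "significant",
                                 "not significant"), format(round(da_p, 4)),
                          ifelse(isTRUE(fa_p < bundle$alpha), "significant",
                                 "not significant"), format(round(fa_p, 4))))
  }
  sig <- bundle$tables$per_landmark_asymmetry
  out <- c(out, "", "=== Per-landmark asymmetry ===",
           sprintf("landmarks with raw P < %g: %s", bundle$alpha,
                   paste(sig$landmark[sig$P < bundle$alpha], collapse = ", ")))
  out
}
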