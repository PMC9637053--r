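# Cohort orchestration: stratification rules, per-subject extraction,
# and the full per-muscle comparison report.

#' Define a cohort stratification rule
#'
#' The comparisons of the study design: patient vs control; presence vs
#' absence of cartilage-endplate damage or Modic changes; Pfirrmann
#' grade > 3 vs <= 3; VAS > 6 vs <= 6. `within` optionally restricts the
#' comparison to a subset first (e.g. CEP damage within patients only).
#'
#' @param variable One of `"group"`, `"cep_damage"`, `"pfirrmann"`,
#'   `"modic"`, `"vas"`.
#' @param name Label for reports; defaults to the variable name.
#' @param within Optional named list of equality filters applied before
#'   splitting, e.g. `list(group = "patient")`.
#' @param threshold Cut-off for graded variables; defaults follow the
#'   study design: Pfirrmann 3, VAS 6.
#' @return A `stratification_rule`.
#' @export
stratification_rule <- function(variable, name = variable, within = NULL,
                                threshold = NULL) {
  variable <- match.arg(variable,
                        c("group", "cep_damage", "pfirrmann", "modic", "vas"))
  if (is.null(threshold))
    threshold <- switch(variable, pfirrmann = 3, vas = 6, NA_real_)
  structure(list(variable = variable, name = name, within = within,
                 threshold = threshold),
            class = "stratification_rule")
}

#' Split a cohort into two subgroups under a rule
#'
#' Subgroup A holds the affected/high side (patients; pathology present;
#' grade or score above threshold), subgroup B the rest. Subjects with a
#' missing stratification value are excluded with a message reporting
#' the count.
#'
#' @param cohort A `cohort_table` (see [read_cohort_table()]).
#' @param rule A [stratification_rule()].
#' @return `list(A, B, n_excluded)` with subject-id vectors; errors if
#'   either subgroup is empty.
#' @export
stratify <- function(cohort, rule) {
  stopifnot(inherits(rule, "stratification_rule"))
  tab <- as.data.frame(cohort)
  for (col in names(rule$within)) {
    if (!col %in% names(tab)) stop("`within` column not found: ", col)
    tab <- tab[!is.na(tab[[col]]) & tab[[col]] == rule$within[[col]], ,
               drop = FALSE]
  }
  v <- rule$variable
  if (!v %in% names(tab))
    stop("stratification variable not in cohort: ", v)
  x <- tab[[v]]
  keep <- !is.na(x)
  n_excluded <- sum(!keep)
  if (n_excluded > 0)
    message(sprintf("stratify(%s): excluded %d subject(s) with missing %s",
                    rule$name, n_excluded, v))
  tab <- tab[keep, , drop = FALSE]
  x <- x[keep]
  inA <- switch(v,
    group = x == "patient",
    cep_damage = as.logical(x),
    modic = as.logical(x),
    pfirrmann = x > rule$threshold,
    vas = x > rule$threshold)
  A <- tab$subject_id[inA]
  B <- tab$subject_id[!inA]
  if (!length(A) || !length(B))
    stop(sprintf("rule '%s' produced an empty subgroup (A: %d, B: %d)",
                 rule$name, length(A), length(B)))
  list(A = A, B = B, n_excluded = n_excluded)
}

#' Extract normalized fat-map profiles for a whole cohort
#'
#' For every subject: read the image and masks listed in the cohort
#' table, locate the CoR from the disc endpoints, and build the
#' smoothed, distance-normalized radial profile of each muscle. When a
#' muscle is segmented as separate left/right masks, the two normalized
#' curves are averaged per subject. Subjects whose mask for a muscle is
#' unusable are dropped from that muscle only (with a message).
#'
#' @param cohort A `cohort_table` including `image`, `mask_*` and disc
#'   endpoint columns.
#' @param data_dir Directory the file paths are relative to.
#' @param n_nodes Nodes of the normalized grid (default 101).
#' @return Named list (per muscle) of: `profiles` (list of
#'   `normalized_profile`), `curves` (matrix subjects x nodes),
#'   `overall` (named overall mean FI% per subject), `subjects`.
#' @export
extract_profiles <- function(cohort, data_dir, n_nodes = 101L) {
  tab <- as.data.frame(cohort)
  need <- c("image", "posterior_row", "posterior_col",
            "anterior_row", "anterior_col")
  if (!all(need %in% names(tab)))
    stop("cohort table lacks image/geometry columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  mask_cols <- grep("^mask_", names(tab), value = TRUE)
  if (!length(mask_cols)) stop("cohort table has no mask_* columns")
  out <- stats::setNames(vector("list", length(FATMAP_MUSCLES)), FATMAP_MUSCLES)
  acc <- list()
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, , drop = FALSE]
    masks <- stats::setNames(
      file.path(data_dir, unlist(row[mask_cols])),
      sub("^mask_", "", mask_cols))
    bundle <- withCallingHandlers(
      read_slice_bundle(file.path(data_dir, row$image), masks, row),
      warning = function(w) {
        message(sprintf("%s: %s", row$subject_id, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    cor <- locate_cor(disc_geometry(
      c(row$posterior_row, row$posterior_col),
      c(row$anterior_row, row$anterior_col)))
    for (m in FATMAP_MUSCLES) {
      mlist <- Filter(function(x) x$muscle == m && x$usable, bundle$masks)
      if (!length(mlist)) {
        if (any(vapply(bundle$masks, function(x) x$muscle == m, logical(1))))
          message(sprintf("%s: unusable %s mask, subject dropped for this muscle",
                          row$subject_id, m))
        next
      }
      curves <- lapply(mlist, function(mm)
        normalize_profile(smooth_profile(
          build_radial_profile(bundle$slice, mm, cor)), n_nodes))
      fi <- rowMeans(do.call(cbind, lapply(curves, `[[`, "fi")))
      prof <- normalized_profile(fi, muscle = m,
                                 side = if (length(mlist) > 1L) "merged"
                                        else mlist[[1L]]$side,
                                 subject_id = row$subject_id)
      om <- mean(vapply(mlist, function(mm)
        overall_mean_fi(bundle$slice, mm), numeric(1)))
      acc[[m]] <- c(acc[[m]], list(list(profile = prof, overall = om,
                                        id = row$subject_id)))
    }
  }
  for (m in FATMAP_MUSCLES) {
    if (is.null(acc[[m]])) next
    profs <- lapply(acc[[m]], `[[`, "profile")
    ids <- vapply(acc[[m]], `[[`, character(1), "id")
    curves <- do.call(rbind, lapply(profs, `[[`, "fi"))
    rownames(curves) <- ids
    out[[m]] <- list(profiles = stats::setNames(profs, ids), curves = curves,
                     overall = stats::setNames(
                       vapply(acc[[m]], `[[`, numeric(1), "overall"), ids),
                     subjects = ids)
  }
  out[!vapply(out, is.null, logical(1))]
}

.config_hash <- function(x) {
  # tiny polynomial fingerprint for the run manifest
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full fat-mapping cohort analysis
#'
#' End-to-end orchestration: extract per-subject normalized profiles,
#' then, for every muscle and every comparison rule, compare the overall
#' mean FI% with an unpaired t-test and the fat-maps with an SPM t-test,
#' and summarise curve peaks and deep-region prevalence. Deterministic
#' given the input data and configuration.
#'
#' @param config Either a named list or a path to a YAML file. Keys:
#'   `data_dir` (required; must contain `cohort.csv` unless
#'   `cohort_csv` is given), `out_dir` (optional; artifacts written when
#'   set), `comparisons` (list of [stratification_rule()] or lists with
#'   the same fields; default: patient vs control), `n_nodes` (101),
#'   `alpha` (0.05), `deep_cut` (33.3), `superficial_cut` (66.7),
#'   `sided` (`"two.sided"`), `seed` (recorded in the manifest).
#' @return A `fatmap_report`: per-subject profiles, and per
#'   muscle x comparison the overall-mean t-test, `spm_result`, group
#'   mean curves, peak table and deep-peak prevalence.
#' @export
run_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$data_dir)) stop("config needs `data_dir`")
  n_nodes <- if (is.null(config$n_nodes)) 101L else as.integer(config$n_nodes)
  alpha <- if (is.null(config$alpha)) 0.05 else config$alpha
  deep_cut <- if (is.null(config$deep_cut)) 100 / 3 else config$deep_cut
  sup_cut <- if (is.null(config$superficial_cut)) 200 / 3
             else config$superficial_cut
  sided <- if (is.null(config$sided)) "two.sided" else config$sided
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  csv <- if (!is.null(config$cohort_csv)) config$cohort_csv
         else file.path(config$data_dir, "cohort.csv")
  cohort <- read_cohort_table(csv)
  rules <- config$comparisons
  if (is.null(rules)) rules <- list(stratification_rule("group"))
  rules <- lapply(rules, function(r) {
    if (inherits(r, "stratification_rule")) r
    else do.call(stratification_rule, r)
  })

  extracted <- extract_profiles(cohort, config$data_dir, n_nodes)

  results <- list()
  for (m in names(extracted)) {
    ex <- extracted[[m]]
    for (r in rules) {
      grp <- tryCatch(stratify(cohort, r), error = function(e)
        stop(sprintf("comparison '%s', muscle %s: %s", r$name, m,
                     conditionMessage(e)), call. = FALSE))
      idsA <- intersect(grp$A, ex$subjects)
      idsB <- intersect(grp$B, ex$subjects)
      if (length(idsA) < 2L || length(idsB) < 2L)
        stop(sprintf("comparison '%s', muscle %s: fewer than 2 usable subjects per subgroup",
                     r$name, m))
      A <- ex$curves[idsA, , drop = FALSE]
      B <- ex$curves[idsB, , drop = FALSE]
      spm <- spm_ttest2(A, B, alpha = alpha, sided = sided,
                        comparison = sprintf("%s / %s", m, r$name))
      om <- unpaired_ttest(ex$overall[idsA], ex$overall[idsB])
      results[[m]][[r$name]] <- list(
        rule = r, subjects = list(A = idsA, B = idsB),
        overall = c(mean_A = mean(ex$overall[idsA]),
                    mean_B = mean(ex$overall[idsB]),
                    diff = mean(ex$overall[idsA]) - mean(ex$overall[idsB]),
                    t = om$t, p = om$p),
        spm = spm,
        mean_curve_A = colMeans(A), mean_curve_B = colMeans(B))
    }
    results[[m]]$peaks <- peak_table(ex$profiles, deep_cut, sup_cut)
    results[[m]]$deep_prevalence <-
      peak_prevalence(ex$profiles, region = "deep",
                      deep_cut = deep_cut, superficial_cut = sup_cut)
  }

  report <- structure(
    list(results = results, extracted = extracted, cohort = cohort,
         settings = list(n_nodes = n_nodes, alpha = alpha,
                         deep_cut = deep_cut, superficial_cut = sup_cut,
                         sided = sided, seed = seed)),
    class = "fatmap_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir, config)
  report
}

#' Write a fatmap report to disk
#'
#' Profiles and peaks as CSV, one SPM JSON per muscle x comparison, and
#' a run manifest (package version, config fingerprint, seed). Output is
#' byte-identical across reruns with the same inputs.
#'
#' @param report A `fatmap_report` from [run_analysis()].
#' @param out_dir Output directory.
#' @param config The configuration that produced the report.
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir, config = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  prof_rows <- list()
  for (m in names(report$extracted)) {
    ex <- report$extracted[[m]]
    for (id in ex$subjects)
      prof_rows[[paste(m, id)]] <- data.frame(
        subject_id = id, muscle = m,
        node_percent = report$extracted[[m]]$profiles[[id]]$nodes,
        fi_percent = report$extracted[[m]]$profiles[[id]]$fi)
  }
  utils::write.csv(do.call(rbind, prof_rows),
                   file.path(out_dir, "profiles.csv"), row.names = FALSE)
  peaks <- do.call(rbind, lapply(names(report$results), function(m)
    report$results[[m]]$peaks))
  utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
  for (m in names(report$results)) {
    res <- report$results[[m]]
    for (nm in setdiff(names(res), c("peaks", "deep_prevalence"))) {
      r <- res[[nm]]
      obj <- list(
        comparison = r$spm$comparison, muscle = m, rule = nm,
        group_sizes = as.list(r$spm$group_sizes),
        overall = as.list(r$overall),
        t = r$spm$field$t, t_star = r$spm$field$t_star,
        fwhm = r$spm$field$fwhm, df = r$spm$field$df,
        alpha = r$spm$field$alpha, sided = r$spm$field$sided,
        clusters = r$spm$clusters,
        mean_curve_A = r$mean_curve_A, mean_curve_B = r$mean_curve_B)
      jsonlite::write_json(obj,
        file.path(out_dir, sprintf("spm_%s_%s.json", m, nm)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
    }
  }
  manifest <- list(
    package = "fatmapr",
    version = as.character(utils::packageVersion("fatmapr")),
    config_hash = .config_hash(config[order(names(config))]),
    seed = report$settings$seed, settings = report$settings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fatmap_report <- function(x, ...) {
  cat(sprintf("<fatmap_report> %d muscles, %d subjects\n",
              length(x$results), nrow(x$cohort)))
  for (m in names(x$results)) {
    res <- x$results[[m]]
    cat(sprintf("  %s (deep-peak prevalence %.1f%%)\n", m,
                100 * res$deep_prevalence))
    for (nm in setdiff(names(res), c("peaks", "deep_prevalence"))) {
      r <- res[[nm]]
      cat(sprintf("    %s: overall dFI = %.2f (p = %.3g), %d cluster(s)\n",
                  nm, r$overall["diff"], r$overall["p"], nrow(r$spm$clusters)))
    }
  }
  invisible(x)
}
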