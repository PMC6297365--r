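## End-to-end orchestration: configuration, input validation, the staged
## analysis (quantify -> morphometry -> agreement -> models) and report
## serialisation. Works identically from a synthetic bundle or from
## user-supplied files (images + landmarks + ratings + species table), so a
## deposited dataset can be re-analysed by pointing `paths` at it.

#' Build a study configuration
#'
#' Exactly one of `synthetic` (arguments for [synth_study()]) and `paths`
#' (locations of user data: `images` dir, `landmarks` file, `beauty` and
#' `humanlikeness` rating CSVs, `species` CSV with group/lg columns) must be
#' given.
#'
#' @param synthetic list of [synth_study()] arguments, or NULL.
#' @param paths list of input paths, or NULL.
#' @param n_perm permutations for the RDA tests.
#' @param alpha significance level used throughout.
#' @param edge_threshold Sobel threshold for the pattern score.
#' @param nose_convention passed to [derive_traits()].
#' @param rda_response "raters" (species x raters score matrix) or
#'   "gender_means" (species x mean male/female score).
#' @param groups_subset optional subset of groups to model separately
#'   (default: all three).
#' @param seed master seed for every stochastic stage.
#' @return object of class `study_config`.
#' @export
study_config <- function(synthetic = list(), paths = NULL, n_perm = 999,
                         alpha = 0.05, edge_threshold = 0.1,
                         nose_convention = "as_printed",
                         rda_response = c("raters", "gender_means"),
                         groups_subset = NULL, seed = 1) {
  has_synth <- !is.null(synthetic)
  has_paths <- !is.null(paths)
  if (has_synth == has_paths)
    stopf("exactly one of 'synthetic' and 'paths' must be given")
  structure(list(synthetic = synthetic, paths = paths, n_perm = n_perm,
                 alpha = alpha, edge_threshold = edge_threshold,
                 nose_convention = nose_convention,
                 rda_response = match.arg(rda_response),
                 groups_subset = groups_subset, seed = seed),
            class = "study_config")
}

#' Validate user-supplied study inputs
#'
#' Checks image alpha channels, landmark counts, rating completeness and
#' range, and species-id joins, returning a report instead of stopping at the
#' first problem.
#'
#' @param paths list as in [study_config()].
#' @return data.frame of violations (`component`, `id`, `message`); empty
#'   when everything validates.
#' @export
validate_inputs <- function(paths) {
  bad <- list()
  note <- function(component, id, message)
    bad[[length(bad) + 1]] <<- data.frame(component = component, id = id,
                                          message = message,
                                          stringsAsFactors = FALSE)
  lms <- NULL
  if (!is.null(paths$landmarks)) {
    lms <- tryCatch(load_landmarks(paths$landmarks),
                    error = function(e) { note("landmarks", paths$landmarks,
                                               conditionMessage(e)); NULL })
  }
  if (!is.null(paths$images) && dir.exists(paths$images)) {
    for (f in list.files(paths$images, pattern = "\\.(png|tif|tiff)$",
                         ignore.case = TRUE, full.names = TRUE)) {
      img <- tryCatch(read_stimulus(f), error = function(e) NULL)
      if (is.null(img)) { note("images", basename(f), "unreadable"); next }
      if (all(img[, , 4] >= 0.5))
        note("images", basename(f), "no transparent background pixels")
    }
  }
  for (nm in c("beauty", "humanlikeness")) {
    if (is.null(paths[[nm]])) next
    df <- tryCatch(read.csv(paths[[nm]], check.names = FALSE),
                   error = function(e) { note(nm, paths[[nm]], "unreadable"); NULL })
    if (is.null(df)) next
    sc <- df[, setdiff(names(df), c("rater_id", "gender", "age")), drop = FALSE]
    for (j in names(sc)) {
      v <- sc[[j]]
      if (anyNA(v)) note(nm, j, "missing rating cells")
      out <- which(!is.na(v) & (v < 1 | v > 7 | v != round(v)))
      for (i in out)
        note(nm, j, sprintf("rating out of 1..7 for rater %s: %s",
                            df$rater_id[i] %||% i, v[i]))
    }
  }
  if (!is.null(paths$species) && !is.null(lms)) {
    sp <- tryCatch(read.csv(paths$species), error = function(e) NULL)
    if (!is.null(sp) && "species_id" %in% names(sp)) {
      miss <- setdiff(sp$species_id, names(lms))
      for (m in miss) note("join", m, "species has no landmark record")
    }
  }
  if (!length(bad))
    return(data.frame(component = character(0), id = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  do.call(rbind, bad)
}

## Assemble the per-species analysis table from the stage outputs.
build_species_table <- function(profiles, covs, beauty, humanlike) {
  ids <- covs$species_id
  mean_beauty <- colMeans(beauty$scores)[ids]
  mean_hl <- colMeans(humanlike$scores)[ids]
  tab <- data.frame(
    species_id = ids, genus_id = covs$genus_id, group = covs$group,
    factor1_outer = covs$factor1_outer, factor2_inner = covs$factor2_inner,
    lg = covs$lg, human_likeness = mean_hl, mean_beauty = mean_beauty,
    stringsAsFactors = FALSE)
  pr <- profiles[match(ids, profiles$image_id), ]
  tab$reddish_brown <- pr$red_t
  tab$orange_col <- pr$orange_t
  tab$yellowish_brown <- pr$yellow_t
  tab$bluish_tint <- pr$bluish_t
  tab$mean_lightness <- pr$mean_lightness
  tab$mean_saturation <- pr$mean_saturation
  tab$pattern <- pr$pattern
  tab
}

#' Run the full study pipeline
#'
#' Executes the stages in order - colour quantification, morphometry (traits,
#' factors, CVA, PCA), rater agreement (ICCs, gender screen, MANOVA), species
#' table assembly, group comparison (Tukey on the inverted scale), full and
#' AIC-reduced linear models (all species and per group), RDA with forward
#' model building and sequential permutation tests, and the LOWESS
#' human-likeness curve for the catarrhines. Fully deterministic under the
#' config seed.
#'
#' @param config a [study_config()].
#' @return object of class `study_results`, a list of tables and fitted
#'   objects with a provenance block.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  t0 <- Sys.time()
  if (!is.null(config$synthetic)) {
    study <- do.call(synth_study, modifyList(list(seed = config$seed),
                                             config$synthetic))
    images <- study$images
    landmarks <- study$landmarks
    beauty <- study$beauty_ratings
    humanlike <- study$humanlikeness_ratings
    species_meta <- spec_covariates(study$panel)[, c("species_id", "genus_id",
                                                     "group", "lg")]
    names(species_meta)[4] <- "lg"
  } else {
    p <- config$paths
    rep_v <- validate_inputs(p)
    if (nrow(rep_v))
      stopf("input validation failed (%d problem(s)); first: %s / %s / %s",
            nrow(rep_v), rep_v$component[1], rep_v$id[1], rep_v$message[1])
    landmarks <- load_landmarks(p$landmarks)
    beauty <- read_ratings_csv(p$beauty)
    humanlike <- read_ratings_csv(p$humanlikeness)
    sp <- read.csv(p$species, stringsAsFactors = FALSE)
    species_meta <- sp[, intersect(c("species_id", "genus_id", "group", "lg",
                                     "male_weight", "female_weight"), names(sp))]
    if (!"lg" %in% names(species_meta) &&
        all(c("male_weight", "female_weight") %in% names(species_meta)))
      species_meta$lg <- lg_ratio(species_meta$male_weight,
                                  species_meta$female_weight)
    images <- NULL
    if (!is.null(p$images)) {
      files <- list.files(p$images, pattern = "\\.(png|tif|tiff)$",
                          ignore.case = TRUE, full.names = TRUE)
      images <- setNames(lapply(files, read_stimulus),
                         tools::file_path_sans_ext(basename(files)))
    }
    study <- NULL
  }
  ## stage 1: colour quantification
  profiles <- do.call(rbind, lapply(names(images), function(id) {
    pr <- color_profile(images[[id]], edge_threshold = config$edge_threshold)
    data.frame(image_id = id, t(pr$fractions),
               t(setNames(pr$transformed_fractions, paste0(COLOR_CLASSES, "_t"))),
               mean_lightness = pr$mean_lightness,
               mean_saturation = pr$mean_saturation,
               pattern = pr$pattern, n_opaque = pr$n_opaque,
               stringsAsFactors = FALSE)
  }))
  ## stage 2: morphometry
  traits <- traits_table(landmarks, nose_convention = config$nose_convention)
  fac <- morpho_factors(traits, n_factors = 2)
  grp <- species_meta$group[match(rownames(traits), species_meta$species_id)]
  cva_res <- cva(traits, grp)
  pca_res <- pca(traits)
  covs <- species_meta[match(rownames(traits), species_meta$species_id), ]
  covs$factor1_outer <- fac$scores[, 1]
  covs$factor2_inner <- fac$scores[, 2]
  ## stage 3: agreement
  icc_pooled <- icc_consistency(beauty)
  g <- beauty$rater_meta$gender
  icc_by_gender <- lapply(c(male = "male", female = "female"), function(gg)
    if (sum(g == gg, na.rm = TRUE) >= 2)
      icc_consistency(beauty$scores[g == gg, , drop = FALSE]) else NULL)
  icc_humanlike <- icc_consistency(humanlike)
  screen <- tryCatch(gender_screen(beauty, alpha = config$alpha),
                     error = function(e) NULL)
  wilks <- if (!all(is.na(beauty$rater_meta$gender)))
    suppressWarnings(manova_wilks(beauty$scores,
                                  data.frame(age = beauty$rater_meta$age,
                                             gender = beauty$rater_meta$gender),
                                  formula = ~ age * gender)) else NULL
  ## stage 4: species table + models
  sptab <- build_species_table(profiles, covs, beauty, humanlike)
  inv_means <- 8 - sptab$mean_beauty  # display scale: higher = more beautiful
  tukey <- tukey_hsd(inv_means, sptab$group)
  full_terms <- c("group", "factor1_outer", "factor2_inner", "lg",
                  "human_likeness", "mean_lightness", "pattern",
                  "mean_saturation", "reddish_brown", "orange_col",
                  "yellowish_brown", "bluish_tint")
  fit_group <- function(d, with_group) {
    terms <- if (with_group) full_terms else setdiff(full_terms, "group")
    f <- as.formula(paste("mean_beauty ~", paste(terms, collapse = " + ")))
    full <- fit_lm(f, d)
    list(full = full, reduced = reduce_aic(full, alpha = config$alpha))
  }
  models <- list(all = fit_group(sptab, with_group = TRUE))
  for (gg in (config$groups_subset %||% PRIMATE_GROUPS)) {
    d <- sptab[sptab$group == gg, ]
    if (nrow(d) > length(full_terms) + 2)
      models[[gg]] <- fit_group(d, with_group = FALSE)
  }
  ## stage 5: RDA
  Y <- if (config$rda_response == "raters") {
    t(beauty$scores)[sptab$species_id, , drop = FALSE]
  } else {
    cbind(male = colMeans(beauty$scores[g == "male", , drop = FALSE]),
          female = colMeans(beauty$scores[g == "female", , drop = FALSE]))[sptab$species_id, ]
  }
  cand <- sptab[, c("factor1_outer", "factor2_inner", "lg", "human_likeness",
                    "mean_lightness", "pattern", "mean_saturation",
                    "reddish_brown", "orange_col", "yellowish_brown",
                    "bluish_tint")]
  rda_seeds <- derive_seeds(config$seed + 7, 2)
  rda_sel <- rda_model_build(Y, cand, n_perm = min(config$n_perm, 499),
                             alpha = config$alpha, seed = rda_seeds[1])
  rda_terms <- if (length(rda_sel$selected))
    rda_permutation_terms(Y, cand[, rda_sel$selected, drop = FALSE],
                          n_perm = config$n_perm, seed = rda_seeds[2]) else NULL
  ## stage 6: uncanny-valley curve (catarrhines)
  cat_rows <- sptab$group == "catarrhine"
  uncanny <- if (sum(cat_rows) >= 5) {
    xx <- 8 - sptab$human_likeness[cat_rows]
    yy <- 8 - sptab$mean_beauty[cat_rows]
    data.frame(species_id = sptab$species_id[cat_rows],
               human_likeness = xx, attractiveness = yy,
               lowess_fit = lowess_curve(xx, yy), stringsAsFactors = FALSE)
  } else NULL
  cfg_for_hash <- unclass(config)
  structure(list(
    profiles = profiles, traits = traits, factor_model = fac,
    cva = cva_res, pca = pca_res,
    agreement = list(icc_pooled = icc_pooled, icc_by_gender = icc_by_gender,
                     icc_humanlikeness = icc_humanlike,
                     gender_screen = screen, manova = wilks),
    species_table = sptab, tukey = tukey, models = models,
    rda = list(selection = rda_sel, terms = rda_terms, fit = rda_sel$fit),
    uncanny = uncanny,
    study = study,
    provenance = list(config = cfg_for_hash,
                      config_hash = object_hash(cfg_for_hash),
                      seed = config$seed,
                      package_version = as.character(utils::packageVersion("primface")),
                      r_version = R.version.string,
                      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  ), class = "study_results")
}

#' @export
print.study_results <- function(x, ...) {
  cat("Face-attractiveness study results\n")
  cat(sprintf("  species: %d | pooled beauty ICC single %.3f / average %.3f\n",
              nrow(x$species_table), x$agreement$icc_pooled$icc_single,
              x$agreement$icc_pooled$icc_average))
  if (!is.null(x$rda$fit))
    cat(sprintf("  RDA: %d term(s) selected, %.1f%% variance constrained\n",
                length(x$rda$selection$selected),
                100 * x$rda$fit$proportion_constrained))
  cat(sprintf("  all-species reduced model r^2 = %.3f\n",
              x$models$all$reduced$r_squared))
  invisible(x)
}

## Serialise with stable column order and 6 significant digits.
fmt6 <- function(df) {
  for (j in names(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 6)
  df
}

#' Export study results
#'
#' Writes the result tables as CSV (floats at 6 significant digits, stable
#' column order) and a JSON report (lossless numerics) including the
#' provenance block.
#'
#' @param results a `study_results`.
#' @param dir output directory.
#' @param format "csv", "json" or both.
#' @return vector of written paths, invisibly.
#' @export
export_report <- function(results, dir, format = c("csv", "json")) {
  format <- match.arg(format, several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("csv" %in% format) {
    wcsv <- function(df, name) {
      p <- file.path(dir, paste0(name, ".csv"))
      write.csv(fmt6(as.data.frame(df)), p, row.names = FALSE)
      written <<- c(written, p)
    }
    wcsv(results$profiles, "color_profiles")
    wcsv(data.frame(species_id = rownames(results$traits), results$traits),
         "traits")
    wcsv(results$species_table, "species_table")
    wcsv(results$tukey, "tukey")
    if (!is.null(results$agreement$gender_screen))
      wcsv(results$agreement$gender_screen, "gender_screen")
    if (!is.null(results$rda$terms)) wcsv(results$rda$terms, "rda_terms")
    if (!is.null(results$uncanny)) wcsv(results$uncanny, "uncanny_curve")
    ## Table-1-shaped models file: ANOVA block + coefficient block per model
    blocks <- lapply(names(results$models), function(nm) {
      m <- results$models[[nm]]$reduced
      an <- as.data.frame(m$anova)
      co <- as.data.frame(m$coefficients)
      rbind(
        data.frame(model = nm, block = "anova", term = rownames(an),
                   df = an$Df, statistic = an$`F value`, p = an$`Pr(>F)`,
                   estimate = NA, se = NA, stringsAsFactors = FALSE),
        data.frame(model = nm, block = "coefficients", term = rownames(co),
                   df = NA, statistic = co$`t value`, p = co$`Pr(>|t|)`,
                   estimate = co$Estimate, se = co$`Std. Error`,
                   stringsAsFactors = FALSE))
    })
    wcsv(do.call(rbind, blocks), "models_table1")
  }
  if ("json" %in% format) {
    p <- file.path(dir, "report.json")
    report <- list(
      agreement = list(
        icc_single = results$agreement$icc_pooled$icc_single,
        icc_average = results$agreement$icc_pooled$icc_average,
        icc_humanlikeness_single = results$agreement$icc_humanlikeness$icc_single,
        icc_humanlikeness_average = results$agreement$icc_humanlikeness$icc_average,
        n_gender_significant =
          if (!is.null(results$agreement$gender_screen))
            sum(results$agreement$gender_screen$significant) else NA),
      models = lapply(results$models, function(m)
        list(formula = deparse(m$reduced$formula),
             r_squared = m$reduced$r_squared, aic = m$reduced$aic)),
      rda = list(selected = results$rda$selection$selected,
                 proportion_constrained =
                   if (!is.null(results$rda$fit))
                     results$rda$fit$proportion_constrained else 0),
      cva_accuracy = results$cva$accuracy,
      provenance = results$provenance[c("config_hash", "seed",
                                        "package_version", "r_version")])
    jsonlite::write_json(report, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    written <- c(written, p)
  }
  invisible(written)
}

#' Re-import a JSON study report
#'
#' @param path the `report.json` written by [export_report()].
#' @return the report list.
#' @export
import_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
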