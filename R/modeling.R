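#' Default model covariates
#'
#' The covariate set of the genotype-by-environment models: environmental
#' drivers (PPFD, temperature, humidity, VPD), reflectance descriptors
#' (total reflectance, signal at 685 nm, GNDVI, NDVI, NDVI_II, PRI, MTCI),
#' plant age (DAS), calendar terms (week and month as categories, hour of
#' day numeric) and the identity terms (species, genotype).
#'
#' @return List with elements `continuous` and `categorical` (character
#'   vectors of observation-table column names).
#' @export
lift_covariates <- function() {
  list(
    continuous = c("ppfd", "temperature", "rh", "vpd", "reflectance_sum",
                   "r685", "gndvi", "ndvi", "ndvi_ii", "pri", "mtci",
                   "das", "hour_of_day"),
    categorical = c("species", "genotype", "month", "week")
  )
}

response_column <- function(obs, response) {
  col <- switch(response, fvfm = "fvfm", fr2 = "fr2_ratio",
                fr1 = "fr1_ratio", response)
  if (!col %in% names(obs)) {
    stop("response column '", col, "' not found", call. = FALSE)
  }
  col
}

#' Build a standardized design matrix for penalised regression
#'
#' Continuous covariates are standardized to mean 0, sd 1 on the training
#' data; categorical covariates are one-hot encoded with the (first) level
#' dropped as reference. Rows with missing values in any used column (for
#' example measurements without paired spectral indices) are dropped and
#' counted. Zero-variance covariates are dropped with a warning. The
#' standardization constants and category levels are stored so validation
#' data can be projected onto the identical columns with
#' [design_transform()].
#'
#' @param obs Observation tibble (see [assemble_observations()]).
#' @param response `"fvfm"`, `"fr2"`, `"fr1"` or a column name. The
#'   response is attached unstandardized.
#' @param covariates List with `continuous` and `categorical` character
#'   vectors; defaults to [lift_covariates()].
#' @return A `lift_design` object: `Z` (n x p numeric matrix), `y`,
#'   `response`, `centers`, `scales`, `cat_levels`, `rows_used` (logical
#'   index into `obs`), `n_dropped`.
#' @export
build_design_matrix <- function(obs, response = "fvfm",
                                covariates = lift_covariates()) {
  resp_col <- response_column(obs, response)
  cont <- intersect(covariates$continuous, names(obs))
  cats <- intersect(covariates$categorical, names(obs))
  missing_cov <- setdiff(c(covariates$continuous, covariates$categorical),
                         names(obs))
  if (length(missing_cov)) {
    warning("covariates absent from observations, skipped: ",
            paste(missing_cov, collapse = ", "), call. = FALSE)
  }
  used <- c(resp_col, cont, cats)
  complete <- stats::complete.cases(obs[, used, drop = FALSE])
  if ("env_linked" %in% names(obs)) complete <- complete & obs$env_linked
  n_dropped <- sum(!complete)
  dat <- obs[complete, , drop = FALSE]
  if (nrow(dat) < 2) stop("fewer than 2 complete observations", call. = FALSE)

  centers <- numeric(0); scales <- numeric(0)
  blocks <- list()
  for (v in cont) {
    x <- dat[[v]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) {
      warning("zero-variance covariate dropped: ", v, call. = FALSE)
      next
    }
    centers[v] <- mean(x); scales[v] <- s
    blocks[[v]] <- matrix((x - centers[v]) / s, ncol = 1,
                          dimnames = list(NULL, v))
  }
  cat_levels <- list()
  for (v in cats) {
    lev <- sort(unique(as.character(dat[[v]])))
    if (length(lev) < 2) {
      warning("single-level categorical covariate dropped: ", v,
              call. = FALSE)
      next
    }
    cat_levels[[v]] <- lev
    m <- vapply(lev[-1], function(l) as.numeric(dat[[v]] == l),
                numeric(nrow(dat)))
    colnames(m) <- paste(v, lev[-1], sep = "_")
    blocks[[v]] <- m
  }
  Z <- do.call(cbind, blocks)
  structure(
    list(Z = Z, y = dat[[resp_col]], response = resp_col,
         centers = centers, scales = scales, cat_levels = cat_levels,
         rows_used = complete, n_dropped = n_dropped),
    class = "lift_design"
  )
}

#' Project new observations onto a fitted design
#'
#' Applies the training standardization constants and category encodings to
#' validation data; the resulting matrix has exactly the training columns.
#' Category levels unseen in training map to the reference (all-zero)
#' encoding.
#'
#' @param design A `lift_design` from [build_design_matrix()].
#' @param newdata Observation tibble.
#' @return List with `Z`, `y` (NULL when the response column is absent)
#'   and `rows_used`.
#' @export
design_transform <- function(design, newdata) {
  stopifnot(inherits(design, "lift_design"))
  cont <- names(design$centers)
  cats <- names(design$cat_levels)
  used <- c(cont, cats)
  if (!all(used %in% names(newdata))) {
    stop("schema error: newdata lacks columns ",
         paste(setdiff(used, names(newdata)), collapse = ", "),
         call. = FALSE)
  }
  complete <- stats::complete.cases(newdata[, used, drop = FALSE])
  if ("env_linked" %in% names(newdata)) complete <- complete & newdata$env_linked
  dat <- newdata[complete, , drop = FALSE]
  blocks <- list()
  for (v in cont) {
    blocks[[v]] <- matrix((dat[[v]] - design$centers[v]) / design$scales[v],
                          ncol = 1, dimnames = list(NULL, v))
  }
  for (v in cats) {
    lev <- design$cat_levels[[v]]
    m <- vapply(lev[-1], function(l) as.numeric(dat[[v]] == l),
                numeric(nrow(dat)))
    if (nrow(dat) == 1) m <- matrix(m, nrow = 1)
    colnames(m) <- paste(v, lev[-1], sep = "_")
    blocks[[v]] <- m
  }
  Z <- do.call(cbind, blocks)
  y <- if (design$response %in% names(dat)) dat[[design$response]] else NULL
  list(Z = Z, y = y, rows_used = complete)
}

#' Fit an L1-penalised (Lasso) model with internal cross-validation
#'
#' Random-effects-style model `y = mu + Z u + e` with the coefficient
#' vector `u` penalised by the L1 norm; the penalty scale lambda is chosen
#' at the minimum mean cross-validated error over a 100-point logarithmic
#' path spanning four decades below the full-shrinkage lambda. Folds are
#' assigned by a seeded shuffle at the observation level. Solved by
#' coordinate descent (glmnet); columns are already standardized by
#' [build_design_matrix()], so internal re-standardization is off.
#'
#' @param design A `lift_design`.
#' @param folds Number of CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @return A `lift_lasso` object: `mu` (intercept), `u` (named coefficient
#'   vector, many exactly zero), `lambda`, `cv_curve` (tibble lambda /
#'   cvm / cvsd / nonzero), `design`, `seed`.
#' @export
fit_lasso_cv <- function(design, folds = 10, seed = 1) {
  stopifnot(inherits(design, "lift_design"))
  n <- length(design$y)
  if (!(n > folds && folds >= 2)) {
    stop("need n > folds >= 2", call. = FALSE)
  }
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  cvfit <- glmnet::cv.glmnet(design$Z, design$y, alpha = 1, foldid = foldid,
                             standardize = FALSE, nlambda = 100,
                             lambda.min.ratio = 1e-4)
  cf <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  u <- cf[-1]
  names(u) <- colnames(design$Z)
  structure(
    list(mu = cf[1], u = u, lambda = cvfit$lambda.min,
         cv_curve = tibble::tibble(lambda = cvfit$lambda, cvm = cvfit$cvm,
                                   cvsd = cvfit$cvsd, nonzero = cvfit$nzero),
         design = design, seed = seed, glmnet_fit = cvfit),
    class = "lift_lasso"
  )
}

#' @export
print.lift_lasso <- function(x, ...) {
  cat(sprintf(
    "<lift_lasso> response %s: lambda = %.4g, %d / %d nonzero coefficients\n",
    x$design$response, x$lambda, sum(x$u != 0), length(x$u)))
  invisible(x)
}

#' Predict from a fitted Lasso model
#'
#' `yhat = mu + Z u`, with `Z` built from `newdata` using the training
#' standardization constants.
#'
#' @param object A `lift_lasso` fit.
#' @param newdata Observation tibble; omit to return training-set
#'   predictions.
#' @param ... Unused.
#' @return When `newdata` is given, a list with `predicted`, `observed`
#'   (NULL if the response is absent) and `rows_used`; otherwise the
#'   numeric training predictions.
#' @export
predict.lift_lasso <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(drop(object$design$Z %*% object$u) + object$mu)
  }
  td <- design_transform(object$design, newdata)
  if (!identical(colnames(td$Z), names(object$u))) {
    stop("schema error: design columns do not match the fit", call. = FALSE)
  }
  list(predicted = drop(td$Z %*% object$u) + object$mu, observed = td$y,
       rows_used = td$rows_used)
}

#' Per-genotype prediction accuracy on cell-averaged values
#'
#' Predicted and measured values are first averaged within (genotype, day,
#' hour) cells, then the Pearson correlation between the cell means is
#' computed per genotype — accuracy defined on averaged values, matching
#' how diurnal prediction accuracy is usually reported for canopy scans.
#'
#' @param predicted,observed Numeric vectors.
#' @param genotype,date,hour Grouping vectors of the same length.
#' @param min_cells Minimum number of cells required per genotype.
#' @return Tibble with `genotype`, `n_cells`, `r` (NA with `flag` set when
#'   undefined, e.g. constant values or too few cells).
#' @export
validate_accuracy <- function(predicted, observed, genotype, date, hour,
                              min_cells = 3) {
  stopifnot(length(predicted) == length(observed),
            length(observed) == length(genotype))
  cells <- tibble::tibble(predicted = predicted, observed = observed,
                          genotype = genotype, date = date, hour = hour) |>
    dplyr::summarise(predicted = mean(.data$predicted),
                     observed = mean(.data$observed),
                     .by = c("genotype", "date", "hour"))
  cells |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      r = if (dplyr::n() >= min_cells && stats::sd(.data$observed) > 0 &&
              stats::sd(.data$predicted) > 0)
        stats::cor(.data$predicted, .data$observed) else NA_real_,
      .by = "genotype"
    ) |>
    dplyr::mutate(flag = ifelse(is.na(.data$r), "undefined", ""))
}

#' Split observations into training and validation partitions
#'
#' `"half-days"` assigns alternate calendar days to training and
#' validation (deterministic by day rank: the 1st, 3rd, 5th ... measured
#' day trains); with an odd number of days the training partition gets the
#' extra day. `"half-days-random"` instead shuffles the day assignment
#' with `seed`. `"by-season"` trains on all observations of one labelled
#' season and validates on the rest.
#'
#' @param obs Observation tibble with a `date` column (and `season` for
#'   the seasonal scheme).
#' @param scheme Partitioning scheme.
#' @param train_season Season label used for training (scheme
#'   `"by-season"`).
#' @param seed Seed for the randomised variant.
#' @return List with `train` and `validation` tibbles.
#' @export
split_train_validation <- function(obs,
                                   scheme = c("half-days",
                                              "half-days-random",
                                              "by-season"),
                                   train_season = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  if (scheme %in% c("half-days", "half-days-random")) {
    days <- sort(unique(obs$date))
    if (length(days) < 2) {
      stop("configuration error: need >= 2 distinct days", call. = FALSE)
    }
    if (scheme == "half-days") {
      train_days <- days[seq(1, length(days), by = 2)]
    } else {
      set.seed(seed)
      train_days <- sort(sample(days, ceiling(length(days) / 2)))
    }
    train <- obs[obs$date %in% train_days, , drop = FALSE]
    validation <- obs[!obs$date %in% train_days, , drop = FALSE]
  } else {
    if (!"season" %in% names(obs) || length(unique(obs$season)) < 2) {
      stop("configuration error: by-season split needs >= 2 seasons",
           call. = FALSE)
    }
    if (is.null(train_season)) train_season <- sort(unique(obs$season))[1]
    train <- obs[obs$season == train_season, , drop = FALSE]
    validation <- obs[obs$season != train_season, , drop = FALSE]
  }
  list(train = train, validation = validation)
}

# short factor names -> formula terms on the observation table
partition_term <- function(name) {
  switch(name,
         temperature = "temperature",
         sqrt_temperature = "I(sqrt(pmax(temperature, 0)))",
         sqrt_ppfd = "I(sqrt(pmax(ppfd, 0)))",
         month = "factor(month)",
         week = "factor(week)",
         species = , crop = "factor(species)",
         hour = "factor(hour_of_day)",
         date = "factor(date)",
         genotype = "factor(genotype)",
         plot = "factor(plot_id)",
         das = "das",
         name)
}

# observation-table columns a factor term depends on
partition_vars <- function(name) {
  all.vars(str2lang(partition_term(name)))
}

#' Sequential (Type-I) sum-of-squares variance partition
#'
#' Fits an ordinary linear model with the factors entered in the given
#' order and reports each factor's sequential sum of squares as a
#' percentage of the total — the explained-variance decomposition used to
#' rank environmental drivers of the fluorescence parameters. The default
#' order mirrors the seasonal analysis: temperature first, then calendar
#' and identity terms, with the square-root temperature term last.
#'
#' @param obs Observation tibble.
#' @param response `"fvfm"`, `"fr2"` or a column name.
#' @param factors Character vector of factor names in entry order. Known
#'   names (`temperature`, `sqrt_temperature`, `month`, `species`/`crop`,
#'   `hour`, `date`, `genotype`, `plot`, `das`, `week`, `ppfd`,
#'   `sqrt_ppfd`, `pri`, ...) are mapped to model terms; anything else is
#'   used verbatim as a formula term.
#' @return A `variance_partition`: tibble with `factor`, `df`, `sum_sq`,
#'   `mean_sq`, `f_value`, `pct_explained`, including the residual row;
#'   the total SS is stored in the `total_ss` attribute.
#' @export
partition_variance <- function(obs, response = "fr2",
                               factors = c("temperature", "month", "species",
                                           "hour", "date", "genotype",
                                           "plot", "das",
                                           "sqrt_temperature")) {
  resp_col <- response_column(obs, response)
  keep <- character(0)
  for (f in factors) {
    v <- partition_vars(f)
    if (!all(v %in% names(obs))) {
      message("factor skipped (column missing): ", f)
      next
    }
    if (all(vapply(v, function(x) length(unique(obs[[x]])) < 2,
                   logical(1)))) {
      message("factor skipped (constant): ", f)
      next
    }
    keep <- c(keep, f)
  }
  if (!length(keep)) stop("no usable factors", call. = FALSE)
  terms <- vapply(keep, partition_term, character(1))
  used_vars <- unique(c(resp_col, unlist(lapply(keep, partition_vars))))
  dat <- obs[stats::complete.cases(obs[, used_vars, drop = FALSE]), ,
             drop = FALSE]
  fml <- stats::as.formula(paste(resp_col, "~", paste(terms, collapse = "+")))
  fit <- stats::lm(fml, data = dat)
  an <- stats::anova(fit)
  total_ss <- sum(an$`Sum Sq`)
  rn <- rownames(an)
  # fully aliased terms (e.g. DAS after a date factor) are absent from the
  # anova table: report them absorbed with 0 df
  row_for <- match(terms, rn)
  absorbed <- is.na(row_for)
  if (any(absorbed)) {
    message("factor(s) absorbed with 0 df: ",
            paste(keep[absorbed], collapse = ", "))
  }
  pick <- function(col, default = NA_real_) {
    v <- ifelse(absorbed, default, an[[col]][row_for])
    c(v, an[[col]][rn == "Residuals"])
  }
  out <- tibble::tibble(
    factor = c(keep, "Residuals"),
    df = pick("Df", 0),
    sum_sq = pick("Sum Sq", 0),
    mean_sq = pick("Mean Sq"),
    f_value = pick("F value"),
    pct_explained = 100 * sum_sq / total_ss
  )
  attr(out, "total_ss") <- total_ss
  attr(out, "response") <- resp_col
  class(out) <- c("variance_partition", class(out))
  out
}

#' Response-curve fits of a fluorescence parameter against one driver
#'
#' Ordinary least squares of the response on transformed terms of a single
#' predictor, fitted separately per group: the light response uses a
#' square-root PPFD term (per PRI level), the temperature response a
#' square-root term and optionally a squared term (per species or
#' genotype).
#'
#' @param obs Observation tibble.
#' @param response `"fvfm"`, `"fr2"` or a column name.
#' @param predictor Column name of the driver (e.g. `"temperature"`,
#'   `"ppfd"`).
#' @param terms Subset of `c("sqrt", "linear", "square")` (at least one).
#' @param group Optional grouping column name; `NULL` fits one curve.
#' @param min_rows Minimum rows per group (groups below are skipped with a
#'   message).
#' @return Tibble with one row per fitted group: `group`, `n`,
#'   `r_squared`, `intercept` and the requested term coefficients
#'   (`b_sqrt`, `b_linear`, `b_square`; NA when a term was dropped for
#'   collinearity).
#' @export
fit_response_curve <- function(obs, response, predictor,
                               terms = c("sqrt", "linear"),
                               group = NULL, min_rows = 10) {
  resp_col <- response_column(obs, response)
  terms <- match.arg(terms, c("sqrt", "linear", "square"), several.ok = TRUE)
  stopifnot(predictor %in% names(obs))
  term_str <- c(sqrt = "I(sqrt(pmax(x, 0)))", linear = "x",
                square = "I(x^2)")[terms]
  dat <- tibble::tibble(y = obs[[resp_col]], x = obs[[predictor]])
  dat$group <- if (is.null(group)) "all" else as.character(obs[[group]])
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  fml <- stats::as.formula(paste("y ~", paste(term_str, collapse = "+")))

  groups <- sort(unique(dat$group))
  rows <- list()
  for (g in groups) {
    d <- dat[dat$group == g, , drop = FALSE]
    if (nrow(d) < min_rows) {
      message("group skipped (", nrow(d), " rows): ", g)
      next
    }
    fit <- stats::lm(fml, data = d)
    cf <- stats::coef(fit)
    if (anyNA(cf)) message("collinear term(s) dropped for group ", g)
    get_b <- function(t) if (t %in% names(cf)) unname(cf[t]) else NA_real_
    rows[[g]] <- tibble::tibble(
      group = g, n = nrow(d),
      r_squared = summary(fit)$r.squared,
      intercept = unname(cf["(Intercept)"]),
      b_sqrt = if ("sqrt" %in% terms) get_b("I(sqrt(pmax(x, 0)))") else NA_real_,
      b_linear = if ("linear" %in% terms) get_b("x") else NA_real_,
      b_square = if ("square" %in% terms) get_b("I(x^2)") else NA_real_
    )
  }
  if (!length(rows)) stop("no group had enough rows", call. = FALSE)
  dplyr::bind_rows(rows)
}
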