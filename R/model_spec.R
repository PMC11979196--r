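#' Parse a measurement-model description
#'
#' Parses a compact measurement-model syntax where each (non-comment) line
#' defines one latent factor and its observed indicators:
#'
#' ```
#' Leadership =~ q1 + q2 + q3
#' ```
#'
#' Only measurement statements (`=~`) are supported: the engine fits pure
#' confirmatory factor models. Regressions (`~`), residual covariances
#' (`~~`) and cross-loadings (the same indicator under two factors) are
#' rejected with an error.
#'
#' @param text Model syntax: a single string (possibly multi-line) or a
#'   character vector of lines. `#` starts a comment.
#' @param data_kind `"continuous"` (covariance metric) or `"ordinal"`
#'   (latent-response/polychoric metric).
#' @param n_categories For ordinal data: number of response categories per
#'   indicator. Either a single integer (all indicators) or a named integer
#'   vector covering every indicator. Ignored for continuous data.
#' @param identification `"unit_factor_variance"` (factor variances fixed at
#'   1, all loadings free; the default) or `"first_loading_fixed"` (first
#'   loading per factor fixed at 1, factor variances free). The two are
#'   fit-equivalent.
#'
#' @return An object of class `cgfi_model`: list with elements `factors`,
#'   `loadings` (named list factor -> character vector of indicators),
#'   `indicators` (union, order of first appearance), `k`, `data_kind`,
#'   `n_categories`, `identification`.
#' @export
#' @examples
#' parse_model("F1 =~ x1 + x2 + x3")
#' parse_model("A =~ x1 + x2\nB =~ x3 + x4")
parse_model <- function(text,
                        data_kind = c("continuous", "ordinal"),
                        n_categories = NULL,
                        identification = c("unit_factor_variance",
                                           "first_loading_fixed")) {
  data_kind <- match.arg(data_kind)
  identification <- match.arg(identification)
  if (length(text) == 0L || all(!nzchar(text))) {
    stop("model syntax is empty", call. = FALSE)
  }
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("model syntax is empty", call. = FALSE)

  factors <- character(0)
  loadings <- list()
  for (ln in lines) {
    if (grepl("~~", ln, fixed = TRUE) ||
        (grepl("~", ln, fixed = TRUE) && !grepl("=~", ln, fixed = TRUE))) {
      stop("unsupported statement (only '=~' measurement lines are allowed): ",
           sQuote(ln), call. = FALSE)
    }
    parts <- strsplit(ln, "=~", fixed = TRUE)[[1]]
    if (length(parts) != 2L) {
      stop("cannot parse model line: ", sQuote(ln), call. = FALSE)
    }
    fac <- trimws(parts[1])
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", fac)) {
      stop("invalid factor name in line: ", sQuote(ln), call. = FALSE)
    }
    inds <- trimws(strsplit(parts[2], "+", fixed = TRUE)[[1]])
    if (any(!nzchar(inds))) {
      stop("empty indicator in line: ", sQuote(ln), call. = FALSE)
    }
    bad <- inds[!grepl("^[A-Za-z][A-Za-z0-9_.]*$", inds)]
    if (length(bad)) {
      stop("invalid indicator name(s) ", paste(sQuote(bad), collapse = ", "),
           " in line: ", sQuote(ln), call. = FALSE)
    }
    if (anyDuplicated(inds)) {
      stop("duplicate indicator within factor ", sQuote(fac), ": ",
           paste(sQuote(inds[duplicated(inds)]), collapse = ", "),
           call. = FALSE)
    }
    if (fac %in% factors) {
      stop("factor ", sQuote(fac), " defined more than once", call. = FALSE)
    }
    factors <- c(factors, fac)
    loadings[[fac]] <- inds
  }

  all_inds <- unlist(loadings, use.names = FALSE)
  if (anyDuplicated(all_inds)) {
    stop("cross-loadings are not supported: indicator(s) ",
         paste(sQuote(unique(all_inds[duplicated(all_inds)])), collapse = ", "),
         " appear under more than one factor", call. = FALSE)
  }
  indicators <- all_inds
  k <- length(indicators)
  if (k < 2L) stop("a model needs at least 2 observed variables", call. = FALSE)

  nc <- NULL
  if (data_kind == "ordinal") {
    if (is.null(n_categories)) {
      stop("n_categories is required for ordinal data", call. = FALSE)
    }
    if (length(n_categories) == 1L && is.null(names(n_categories))) {
      nc <- stats::setNames(rep(as.integer(n_categories), k), indicators)
    } else {
      missing_nc <- setdiff(indicators, names(n_categories))
      if (length(missing_nc)) {
        stop("n_categories missing for: ",
             paste(missing_nc, collapse = ", "), call. = FALSE)
      }
      nc <- stats::setNames(as.integer(n_categories[indicators]), indicators)
    }
    if (any(nc < 2L)) stop("n_categories must all be >= 2", call. = FALSE)
  } else if (!is.null(n_categories)) {
    stop("n_categories is only meaningful for ordinal data", call. = FALSE)
  }

  structure(
    list(factors = factors, loadings = loadings, indicators = indicators,
         k = k, data_kind = data_kind, n_categories = nc,
         identification = identification),
    class = "cgfi_model"
  )
}

#' Serialize a model back to its syntax
#'
#' Inverse of [parse_model()]: `parse_model(deparse_model(spec))` recovers an
#' identical structure.
#'
#' @param spec A `cgfi_model`.
#' @return A single string of model syntax.
#' @export
deparse_model <- function(spec) {
  stopifnot(inherits(spec, "cgfi_model"))
  paste(vapply(spec$factors, function(f) {
    paste(f, "=~", paste(spec$loadings[[f]], collapse = " + "))
  }, character(1)), collapse = "\n")
}

#' @export
print.cgfi_model <- function(x, ...) {
  cat("CFA measurement model (", x$data_kind, " data)\n", sep = "")
  cat(deparse_model(x), "\n")
  cat("k =", x$k, "observed variables;", length(x$factors), "factor(s);",
      "identification:", x$identification, "\n")
  invisible(x)
}

#' Build the free/fixed parameter template of a model
#'
#' Enumerates every model parameter (loadings, factor variances and
#' covariances, uniquenesses, thresholds) with its free/fixed status under
#' the model's identification convention.
#'
#' Continuous data: free parameters are the loadings (all of them under unit
#' factor variance; all but the first per factor when the first loading is
#' fixed at 1, with factor variances free instead), one uniqueness per
#' indicator, and one covariance per factor pair.
#'
#' Ordinal data use the delta parameterization: the implied latent-response
#' variances are fixed at 1, so uniquenesses are derived (1 minus the
#' communality), not free; free parameters are the loadings, the
#' per-indicator thresholds (categories minus one each) and factor
#' covariances.
#'
#' @param spec A `cgfi_model` from [parse_model()].
#' @return An object of class `cgfi_template`: a list with `entries` (a
#'   data.frame with columns `name`, `role`, `status`, `value`) and `p_free`.
#' @export
build_template <- function(spec) {
  stopifnot(inherits(spec, "cgfi_model"))
  name <- character(0); role <- character(0)
  status <- character(0); value <- numeric(0)
  add <- function(n, r, s, v = NA_real_) {
    name <<- c(name, n); role <<- c(role, r)
    status <<- c(status, s); value <<- c(value, v)
  }
  first_fixed <- spec$identification == "first_loading_fixed"

  for (f in spec$factors) {
    inds <- spec$loadings[[f]]
    for (i in seq_along(inds)) {
      nm <- paste0(f, "=~", inds[i])
      if (first_fixed && i == 1L) add(nm, "loading", "fixed", 1.0)
      else add(nm, "loading", "free", 0.7)
    }
  }
  for (f in spec$factors) {
    nm <- paste0(f, "~~", f)
    if (first_fixed) add(nm, "factor_variance", "free", 0.5)
    else add(nm, "factor_variance", "fixed", 1.0)
  }
  nf <- length(spec$factors)
  if (nf > 1L) {
    for (i in 1:(nf - 1L)) for (j in (i + 1L):nf) {
      add(paste0(spec$factors[i], "~~", spec$factors[j]),
          "factor_covariance", "free", 0.0)
    }
  }
  if (spec$data_kind == "continuous") {
    for (v in spec$indicators) {
      add(paste0(v, "~~", v), "uniqueness", "free", 0.3)
    }
  } else {
    for (v in spec$indicators) {
      add(paste0(v, "~~", v), "uniqueness", "fixed", NA_real_)
      for (c in seq_len(spec$n_categories[[v]] - 1L)) {
        add(paste0(v, "|t", c), "threshold", "free", NA_real_)
      }
    }
  }

  entries <- data.frame(name = name, role = role, status = status,
                        value = value, stringsAsFactors = FALSE)
  p_free <- sum(entries$status == "free")
  if (p_free < 1L) stop("model has no free parameters", call. = FALSE)
  structure(list(entries = entries, p_free = p_free), class = "cgfi_template")
}

#' Model degrees of freedom
#'
#' Number of non-redundant sample moments minus the number of free
#' parameters. Continuous (covariance) metric: `k(k+1)/2 - p`. Ordinal
#' (correlation + threshold) metric: `k(k-1)/2 + total thresholds - p`.
#'
#' @param spec A `cgfi_model`.
#' @return Integer degrees of freedom (>= 0; an under-identified model with
#'   negative df is an error).
#' @export
#' @examples
#' model_df(parse_model("F =~ x1 + x2 + x3 + x4 + x5 + x6 + x7"))  # 14
model_df <- function(spec) {
  stopifnot(inherits(spec, "cgfi_model"))
  tmpl <- build_template(spec)
  k <- spec$k
  n_moments <- if (spec$data_kind == "continuous") {
    k * (k + 1L) / 2L
  } else {
    k * (k - 1L) / 2L + sum(spec$n_categories - 1L)
  }
  df <- as.integer(n_moments - tmpl$p_free)
  if (df < 0L) {
    stop("model is under-identified: df = ", df, " (", n_moments,
         " moments, ", tmpl$p_free, " free parameters)", call. = FALSE)
  }
  df
}
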