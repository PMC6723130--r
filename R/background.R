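#' Confidence-interval width from a count of nines
#'
#' Background stringency is conveniently swept as "number of trailing 9s":
#' one nine is alpha 0.9, fifteen nines alpha 0.999999999999999.
#'
#' @param nines integer count of nines.
#' @return alpha fraction in (0, 1).
#' @export
alpha_from_nines <- function(nines) {
  stopifnot(all(nines >= 1))
  1 - 10^(-nines)
}

#' Central Student's-t interval endpoints of a background distribution
#'
#' Each background distribution is a location-scale t: location = mean of
#' the control VAFs, scale = their sample standard deviation, df = n - 1.
#' The central interval containing `alpha` probability mass is
#' `location +/- qt((1+alpha)/2, df) * scale`, with the low endpoint floored
#' at 0 (VAFs cannot be negative). A zero scale collapses the interval to
#' the location for any alpha.
#'
#' @param location,scale,df vectors of t parameters (recycled).
#' @param alpha central probability mass, strictly between 0 and 1.
#' @return list with vectors `low` and `high`.
#' @export
ci_endpoints <- function(location, scale, df, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie strictly between 0 and 1")
  half <- qt((1 + alpha) / 2, df) * scale
  list(low = pmax(0, location - half), high = location + half)
}

key_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

# one row per interior panel position x alternate base, with pooled class ids
panel_key_space <- function(panel) {
  out <- list()
  for (p in seq_len(nrow(panel))) {
    len <- nchar(panel$region_seq[p])
    if (len < 3L) next
    off <- seq.int(1L, len - 2L)  # interior, 0-based offsets 1..len-2
    refs <- substr(rep(panel$region_seq[p], length(off)), off + 1L, off + 1L)
    ctx <- substr(rep(panel$region_seq[p], length(off)), off, off + 2L)
    df <- data.frame(chrom = panel$chrom[p], pos = panel$start[p] + off,
                     ref = refs, context = ctx, stringsAsFactors = FALSE)
    out[[p]] <- df
  }
  pos_tab <- do.call(rbind, out)
  alts <- lapply(seq_len(nrow(pos_tab)), function(i) setdiff(DNA_BASES, pos_tab$ref[i]))
  idx <- rep(seq_len(nrow(pos_tab)), each = 3L)
  keys <- pos_tab[idx, , drop = FALSE]
  keys$alt <- unlist(alts)
  keys$class <- context_class(keys$context, keys$ref, keys$alt)
  rownames(keys) <- NULL
  keys
}

fit_t_row <- function(vafs, outlier_drop, germline_vaf_ceiling) {
  v <- vafs[vafs <= germline_vaf_ceiling]
  if (outlier_drop > 0 && length(v) > outlier_drop)
    v <- sort(v)[seq_len(length(v) - outlier_drop)]
  n <- length(v)
  if (n < 2L) return(NULL)
  c(n = n, df = n - 1L, location = mean(v), scale = sd(v))
}

#' Fit an empirical background model from control samples
#'
#' The central estimator of the package. For every (position, substitution)
#' observed in any control sample, the control VAFs (zero-filled for
#' controls lacking the call, so that absence counts as evidence of a low
#' error rate) are modelled as a Student's t distribution with df = n - 1,
#' location = mean and scale = sample standard deviation; alpha confidence
#' endpoints of each distribution later decide whether a test-sample call
#' rises above background. Control VAFs above `germline_vaf_ceiling` are
#' dropped before fitting (germline heterozygotes are not background), as
#' are the `outlier_drop` highest remaining values per key, to minimise the
#' influence of any true mutations present in the controls.
#'
#' A generic fallback is always fitted alongside: control VAFs pooled by
#' pyrimidine-collapsed (trinucleotide context, alternate) class across all
#' probed positions, governing keys the positional table has never seen.
#' With `kind = "generic"` the positional table is omitted and the fallback
#' governs every call (the context-only model).
#'
#' @param control_calls list of `umivar_calls` (one per control sample);
#'   at least 2 controls are required, 5-10 give a stable background.
#' @param panel an `umivar_panel`.
#' @param alpha default confidence mass used by [filter_variants()]
#'   (recomputable at query time).
#' @param kind `"positional"` (per-position table + generic fallback) or
#'   `"generic"` (context-only).
#' @param outlier_drop number of highest control VAFs removed per key
#'   before fitting (default 1).
#' @param germline_vaf_ceiling control VAFs above this are excluded from
#'   fitting (default 0.25).
#' @param provenance free-text tag, conventionally `"internal"` (controls
#'   from the same experiment as the test samples) or `"external"` (a
#'   different experiment); metadata only.
#' @return an object of class `umivar_background` with components
#'   `positions` (data frame: chrom, pos, ref, alt, n, df, location, scale,
#'   low, high), `generic` (per class), `alpha`, `kind`, `provenance`,
#'   `n_controls`.
#' @export
fit_background <- function(control_calls, panel, alpha = 0.99,
                           kind = c("positional", "generic"),
                           outlier_drop = 1L, germline_vaf_ceiling = 0.25,
                           provenance = "internal") {
  kind <- match.arg(kind)
  if (!is.list(control_calls) || inherits(control_calls, "data.frame"))
    control_calls <- list(control_calls)
  nctl <- length(control_calls)
  if (nctl < 2L)
    stop("insufficient controls: at least 2 control samples are required")

  keyspace <- panel_key_space(panel)
  space_id <- key_id(keyspace$chrom, keyspace$pos, keyspace$ref, keyspace$alt)

  # zero-filled VAF matrix over the union of observed keys
  ids <- lapply(control_calls, function(cc) key_id(cc$chrom, cc$pos, cc$ref, cc$alt))
  seen <- sort(unique(unlist(ids)))
  vmat <- matrix(0, nrow = length(seen), ncol = nctl,
                 dimnames = list(seen, NULL))
  for (j in seq_len(nctl))
    vmat[match(ids[[j]], seen), j] <- control_calls[[j]]$vaf

  positions <- NULL
  if (kind == "positional" && length(seen)) {
    info <- keyspace[match(seen, space_id), , drop = FALSE]
    fits <- lapply(seq_along(seen), function(i)
      fit_t_row(vmat[i, ], outlier_drop, germline_vaf_ceiling))
    keep <- !vapply(fits, is.null, logical(1))
    if (any(keep)) {
      fm <- do.call(rbind, fits[keep])
      positions <- data.frame(info[keep, c("chrom", "pos", "ref", "alt"),
                                   drop = FALSE],
                              n = as.integer(fm[, "n"]),
                              df = as.integer(fm[, "df"]),
                              location = fm[, "location"],
                              scale = fm[, "scale"], stringsAsFactors = FALSE)
      ep <- ci_endpoints(positions$location, positions$scale, positions$df, alpha)
      positions$low <- ep$low
      positions$high <- ep$high
      rownames(positions) <- NULL
    }
  }

  # generic per-class pooling: every probed key contributes one zero-filled
  # VAF per control
  cls <- sort(unique(keyspace$class))
  gen <- lapply(cls, function(cl) {
    rows <- which(keyspace$class == cl)
    m <- match(space_id[rows], seen)
    v <- rep(0, length(rows) * nctl)
    obs <- which(!is.na(m))
    if (length(obs))
      v[rep((seq_len(nctl) - 1L) * length(rows), each = length(obs)) + obs] <-
        as.vector(vmat[m[obs], , drop = FALSE])
    fit_t_row(v, 0L, germline_vaf_ceiling)
  })
  keepg <- !vapply(gen, is.null, logical(1))
  gm <- do.call(rbind, gen[keepg])
  generic <- data.frame(class = cls[keepg], n = as.integer(gm[, "n"]),
                        df = as.integer(gm[, "df"]), location = gm[, "location"],
                        scale = gm[, "scale"], stringsAsFactors = FALSE)
  epg <- ci_endpoints(generic$location, generic$scale, generic$df, alpha)
  generic$low <- epg$low
  generic$high <- epg$high

  structure(list(positions = positions, generic = generic, alpha = alpha,
                 kind = kind, provenance = provenance, n_controls = nctl,
                 outlier_drop = as.integer(outlier_drop),
                 germline_vaf_ceiling = germline_vaf_ceiling),
            class = "umivar_background")
}

#' Positional background from control call sets
#'
#' Spec-level wrapper for [fit_background()] with `kind = "positional"`.
#' @inheritParams fit_background
#' @param ... passed to [fit_background()].
#' @return an `umivar_background`.
#' @export
build_position_background <- function(control_calls, panel, alpha = 0.99,
                                      outlier_drop = 1L, ...) {
  fit_background(control_calls, panel, alpha, kind = "positional",
                 outlier_drop = outlier_drop, ...)
}

#' Generic (trinucleotide-context) background from control call sets
#'
#' Context-only model: control VAFs pooled by pyrimidine-collapsed
#' (trinucleotide context, alternate) class across all probed positions.
#' @inheritParams fit_background
#' @param ... passed to [fit_background()].
#' @return an `umivar_background` of kind `"generic"`.
#' @export
build_generic_background <- function(control_calls, panel, alpha = 0.99, ...) {
  fit_background(control_calls, panel, alpha, kind = "generic", ...)
}

#' @export
print.umivar_background <- function(x, ...) {
  cat(sprintf("umivar background model (%s, %s): %d control(s), alpha %.15g\n",
              x$kind, x$provenance, x$n_controls, x$alpha))
  cat(sprintf("  positional keys: %d; generic classes: %d\n",
              if (is.null(x$positions)) 0L else nrow(x$positions),
              nrow(x$generic)))
  invisible(x)
}

#' @export
#' @method summary umivar_background
summary.umivar_background <- function(object, ...) {
  pos <- object$positions
  out <- list(kind = object$kind, provenance = object$provenance,
              alpha = object$alpha, n_controls = object$n_controls,
              n_keys = if (is.null(pos)) 0L else nrow(pos),
              n_classes = nrow(object$generic),
              location_quartiles = if (!is.null(pos) && nrow(pos))
                quantile(pos$location, c(.25, .5, .75)) else NULL,
              top_classes = head(object$generic[order(-object$generic$location),
                                                c("class", "location", "high")], 5))
  class(out) <- "summary.umivar_background"
  out
}

#' @export
print.summary.umivar_background <- function(x, ...) {
  cat(sprintf("umivar background (%s, %s): %d controls, %d positional keys, %d context classes, alpha %.15g\n",
              x$kind, x$provenance, x$n_controls, x$n_keys, x$n_classes, x$alpha))
  if (!is.null(x$location_quartiles)) {
    cat("  positional location quartiles:\n")
    print(signif(x$location_quartiles, 3))
  }
  cat("  highest-rate context classes:\n")
  print(x$top_classes, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method coef umivar_background
#' @importFrom stats coef quantile
coef.umivar_background <- function(object, ...) {
  if (!is.null(object$positions)) object$positions else object$generic
}

#' Flag calls significantly above background
#'
#' A call is significant when its VAF exceeds the high endpoint of the
#' alpha-central interval of its governing background distribution: the
#' per-key positional distribution if the model has seen that key, else the
#' generic (context, alternate) class. Endpoints are recomputed from the
#' stored t parameters at the requested alpha, so one fitted model serves a
#' whole stringency sweep. The low endpoint is carried for diagnostics but
#' plays no role in calling.
#'
#' @param calls an `umivar_calls`.
#' @param model an `umivar_background`.
#' @param alpha confidence mass; default the model's fitting alpha.
#' @return the calls with added columns `significant` (logical),
#'   `significance` (`"positional"`, `"generic"` when flagged by fallback,
#'   or `"none"`), `bg_high`, `bg_low`; counts in attribute `filter_counts`.
#' @export
filter_variants <- function(calls, model, alpha = NULL) {
  stopifnot(inherits(model, "umivar_background"))
  alpha <- alpha %||% model$alpha
  n <- nrow(calls)
  src <- rep("generic", n)
  hi <- rep(NA_real_, n)
  lo <- rep(NA_real_, n)
  if (!is.null(model$positions) && nrow(model$positions)) {
    pid <- key_id(model$positions$chrom, model$positions$pos,
                  model$positions$ref, model$positions$alt)
    m <- match(key_id(calls$chrom, calls$pos, calls$ref, calls$alt), pid)
    hitp <- !is.na(m)
    if (any(hitp)) {
      ep <- ci_endpoints(model$positions$location[m[hitp]],
                         model$positions$scale[m[hitp]],
                         model$positions$df[m[hitp]], alpha)
      hi[hitp] <- ep$high
      lo[hitp] <- ep$low
      src[hitp] <- "positional"
    }
  }
  gidx <- which(src == "generic")
  if (length(gidx)) {
    cls <- context_class(calls$context[gidx], calls$ref[gidx], calls$alt[gidx])
    m <- match(cls, model$generic$class)
    ok <- !is.na(m)
    if (any(ok)) {
      ep <- ci_endpoints(model$generic$location[m[ok]],
                         model$generic$scale[m[ok]],
                         model$generic$df[m[ok]], alpha)
      hi[gidx[ok]] <- ep$high
      lo[gidx[ok]] <- ep$low
    }
    src[gidx[!ok]] <- "none"
  }
  significant <- !is.na(hi) & calls$vaf > hi
  out <- calls
  out$significant <- significant
  out$significance <- ifelse(significant, src, "none")
  out$bg_high <- hi
  out$bg_low <- lo
  attr(out, "filter_counts") <- list(
    n_calls = n, n_significant = sum(significant),
    n_positional = sum(significant & src == "positional"),
    n_generic_fallback = sum(significant & src == "generic"),
    alpha = alpha)
  out
}

#' @export
predict.umivar_background <- function(object, newdata, alpha = NULL, ...) {
  filter_variants(newdata, object, alpha = alpha)
}

#' Serialize a background model
#'
#' One TSV per table (positional keys and generic classes) plus a JSON
#' header file with the model metadata.
#'
#' @param model an `umivar_background`.
#' @param prefix output path prefix; writes `<prefix>.positions.tsv`,
#'   `<prefix>.generic.tsv`, `<prefix>.json`.
#' @return invisibly, the written paths.
#' @export
write_background <- function(model, prefix) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("write_background requires the jsonlite package")
  paths <- c(positions = paste0(prefix, ".positions.tsv"),
             generic = paste0(prefix, ".generic.tsv"),
             meta = paste0(prefix, ".json"))
  pos <- model$positions
  if (is.null(pos))
    pos <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), n = integer(0), df = integer(0),
                      location = numeric(0), scale = numeric(0),
                      low = numeric(0), high = numeric(0))
  write.table(pos, paths["positions"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model$generic, paths["generic"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- model[c("alpha", "kind", "provenance", "n_controls", "outlier_drop",
                  "germline_vaf_ceiling")]
  jsonlite::write_json(meta, paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Load a serialized background model
#'
#' @param prefix the prefix passed to [write_background()].
#' @return an `umivar_background`.
#' @export
read_background <- function(prefix) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    stop("read_background requires the jsonlite package")
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  pos <- read.delim(paste0(prefix, ".positions.tsv"), stringsAsFactors = FALSE)
  gen <- read.delim(paste0(prefix, ".generic.tsv"), stringsAsFactors = FALSE)
  structure(list(positions = if (nrow(pos)) pos else NULL, generic = gen,
                 alpha = meta$alpha, kind = meta$kind,
                 provenance = meta$provenance, n_controls = meta$n_controls,
                 outlier_drop = meta$outlier_drop,
                 germline_vaf_ceiling = meta$germline_vaf_ceiling),
            class = "umivar_background")
}

#' Substitution spectrum of a call set
#'
#' Relative prevalence of substitution classes (six pyrimidine-collapsed
#' classes by default) and of trinucleotide-context classes, either
#' count-weighted (each call counts once) or frequency-weighted (calls
#' weighted by VAF).
#'
#' @param calls an `umivar_calls` (context column required for the
#'   per-context table).
#' @param collapse_complement merge complementary changes (default TRUE).
#' @param weight `"count"` or `"vaf"`.
#' @return object of class `umivar_spectrum`: list with `classes` (named
#'   prevalence vector summing to 1) and `contexts` (per context class).
#' @export
mutation_spectrum <- function(calls, collapse_complement = TRUE,
                              weight = c("count", "vaf")) {
  weight <- match.arg(weight)
  if (!nrow(calls)) stop("spectrum of an empty call set is undefined")
  w <- if (weight == "count") rep(1, nrow(calls)) else calls$vaf
  cls <- if (collapse_complement) substitution_class(calls$ref, calls$alt)
         else paste0(calls$ref, ">", calls$alt)
  classes <- tapply(w, cls, sum)
  classes <- classes / sum(classes)
  ctx <- context_class(calls$context, calls$ref, calls$alt)
  okc <- !is.na(ctx)
  contexts <- if (any(okc)) {
    ct <- tapply(w[okc], ctx[okc], sum)
    ct / sum(ct)
  } else numeric(0)
  structure(list(classes = c(classes), contexts = c(contexts),
                 weight = weight,
                 collapse_complement = collapse_complement),
            class = "umivar_spectrum")
}

#' @export
print.umivar_spectrum <- function(x, ...) {
  cat(sprintf("umivar substitution spectrum (%s-weighted)\n", x$weight))
  print(round(sort(x$classes, decreasing = TRUE), 4))
  invisible(x)
}

#' @export
#' @method plot umivar_spectrum
#' @importFrom graphics barplot
plot.umivar_spectrum <- function(x, ...) {
  barplot(sort(x$classes, decreasing = TRUE), ylab = "relative prevalence",
          xlab = "substitution class", ...)
  invisible(x)
}
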