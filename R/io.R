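# Point-set readers/writers and the end-to-end pipeline driver.

#' Read contours from a point CSV
#'
#' The file must have a header with at least `x,y`; optional columns `z`
#' (default 0), `wall` (default `"endo"`), `phase` (default `NA`). One row
#' per point, rows in boundary order; points are grouped into one contour per
#' unique `(z, wall, phase)` combination, preserving row order within a
#' group.
#'
#' @param path CSV file path.
#' @param closed are the contours closed rings?
#' @return list of [contour()]s, with a `phase` attribute per element.
#' @export
read_point_csv <- function(path, closed = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(df)))
    stop("format error: columns x and y are required in ", path)
  for (col in c("x", "y")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("format error: non-numeric ", col, " at line ",
           if (length(bad)) bad[1L] + 1L else "?", " of ", path)
    }
  }
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  df$z <- if (is.null(df$z)) 0 else as.numeric(df$z)
  if (is.null(df$wall)) df$wall <- "endo"
  if (is.null(df$phase)) df$phase <- NA_character_
  key <- paste(df$z, df$wall, df$phase, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(g) {
    ct <- contour(cbind(g$x, g$y), z = g$z[1L], wall = g$wall[1L],
                  closed = closed)
    attr(ct, "phase") <- g$phase[1L]
    ct
  })
}

#' Write contours to a point CSV
#'
#' Full-precision writer; a write-read round trip reproduces coordinates
#' exactly.
#'
#' @param contours a [contour()] or list of contours.
#' @param path output CSV path.
#' @param phase optional phase label column value (recycled).
#' @return `path`, invisibly.
#' @export
write_point_csv <- function(contours, path, phase = NA_character_) {
  contours <- as_contour_list(contours)
  rows <- do.call(rbind, lapply(seq_along(contours), function(k) {
    ct <- contours[[k]]
    ph <- attr(ct, "phase")
    if (is.null(ph) || is.na(ph)) ph <- phase[min(k, length(phase))]
    data.frame(x = sprintf("%.17g", ct$points[, 1L]),
               y = sprintf("%.17g", ct$points[, 2L]),
               z = sprintf("%.17g", ct$z), wall = ct$wall, phase = ph,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a contour stack as JSON
#'
#' The stack is a list of slices, each with `z`, `wall` and `points` (list of
#' `[x, y]` pairs).
#'
#' @param stack a [contour_stack()].
#' @param path JSON file path.
#' @return `write_stack_json` returns `path` invisibly; `read_stack_json`
#'   returns a [contour_stack()].
#' @export
write_stack_json <- function(stack, path) {
  slices <- lapply(stack$contours, function(ct)
    list(z = ct$z, wall = ct$wall, points = ct$points))
  jsonlite::write_json(list(phase = stack$phase, slices = slices), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_stack_json
#' @export
read_stack_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cts <- lapply(seq_len(nrow(obj$slices)), function(k)
    contour(obj$slices$points[[k]], z = obj$slices$z[k],
            wall = obj$slices$wall[k]))
  contour_stack(cts, phase = obj$phase)
}

#' Run configuration for the pipeline
#'
#' Merges cost and SGD settings with paths and mode into one validated
#' configuration. Unknown keys are rejected.
#'
#' @param scene,model paths to point CSVs, or in-memory contour lists.
#' @param sigma,beta,lambda,sigma_v,grid_side,anneal cost settings, see
#'   [cost_config()].
#' @param mode `"sgd_qn"` or `"qn"`.
#' @param direction `"forward"`, `"reverse"` or `"both"`.
#' @param seed RNG seed for the SGD stage.
#' @param sgd_step0,sgd_decay,sgd_epochs SGD schedule, see [sgd_config()].
#' @param n_sections azimuthal sections for slice equalization.
#' @param out optional JSON output path.
#' @param ... unused; any key not listed above is rejected.
#' @return validated list of class `ssd_run_config`.
#' @export
run_config <- function(scene, model, ..., sigma = NULL, beta = 1,
                       lambda = 0.01, sigma_v = NULL, grid_side = 10L,
                       anneal = FALSE, mode = "sgd_qn", direction = "forward",
                       seed = 0L, sgd_step0 = NULL, sgd_decay = 1e-2,
                       sgd_epochs = 200L, n_sections = 64L, out = NULL) {
  dots <- list(...)
  if (length(dots))
    stop("unknown configuration keys: ",
         paste(if (is.null(names(dots))) "<unnamed>" else names(dots),
               collapse = ", "))
  cfg <- list(scene = scene, model = model, sigma = sigma, beta = beta,
              lambda = lambda, sigma_v = sigma_v, grid_side = grid_side,
              anneal = anneal, mode = mode, direction = direction,
              seed = seed, sgd_step0 = sgd_step0, sgd_decay = sgd_decay,
              sgd_epochs = sgd_epochs, n_sections = n_sections, out = out)
  if (!cfg$mode %in% c("sgd_qn", "qn")) stop("mode must be sgd_qn or qn")
  if (!cfg$direction %in% c("forward", "reverse", "both"))
    stop("direction must be forward, reverse or both")
  structure(cfg, class = "ssd_run_config")
}

load_contours <- function(x) {
  if (is.character(x)) read_point_csv(x) else as_contour_list(x)
}

#' Run the full registration pipeline
#'
#' Loads scene and model contours, equalizes slice sampling along the long
#' axis when the two phases disagree (per wall, interpolating the model stack
#' to the scene z levels), registers the combined walls of each slice,
#' computes APD (and Dice per wall) in the requested direction(s), and
#' serializes parameters, mapped points, displacement vectors and metrics to
#' JSON. Every default filled in (kernel scale, weights, schedule) is
#' recorded in the result so runs are auditable and reproducible.
#'
#' @param cfg an [run_config()].
#' @return the result list (also written to `cfg$out` when set): elements
#'   `config`, `slices` (per-slice diagnostics and metrics), `summary`.
#' @export
run_pipeline <- function(cfg) {
  scene <- load_contours(cfg$scene)
  model <- load_contours(cfg$model)
  scene_z <- vapply(scene, function(ct) ct$z, 0)
  model_z <- vapply(model, function(ct) ct$z, 0)
  zs <- sort(unique(scene_z))

  if (!setequal(scene_z, model_z)) {
    # per wall: interpolate the model stack onto the scene z levels
    model <- unlist(lapply(unique(vapply(model, function(ct) ct$wall, "")),
      function(w) {
        sub <- model[vapply(model, function(ct) ct$wall == w, TRUE)]
        sub <- sub[order(vapply(sub, function(ct) ct$z, 0))]
        if (length(sub) < 2L) return(sub)
        target <- zs[zs >= min(vapply(sub, function(ct) ct$z, 0)) &
                     zs <= max(vapply(sub, function(ct) ct$z, 0))]
        interpolate_stack_along_axis(contour_stack(sub), target,
                                     n_sections = cfg$n_sections)$contours
      }), recursive = FALSE)
    model_z <- vapply(model, function(ct) ct$z, 0)
  }

  ccfg <- cost_config(sigma = cfg$sigma, beta = cfg$beta, lambda = cfg$lambda,
                      sigma_v = cfg$sigma_v, grid_side = cfg$grid_side,
                      anneal = cfg$anneal)
  scfg <- sgd_config(step0 = cfg$sgd_step0, decay = cfg$sgd_decay,
                     epochs = cfg$sgd_epochs, seed = cfg$seed)

  one_direction <- function(sc, mc) {
    res <- register(sc, mc, ccfg, mode = cfg$mode, sgd = scfg)
    met <- registration_metrics(res$mapped,
                                do.call(rbind, lapply(sc, `[[`, "points")))
    walls <- vapply(mc, function(ct) ct$wall, "")
    dm <- tryCatch({
      offs <- c(0L, cumsum(vapply(mc, function(ct) nrow(ct$points), 0L)))
      vapply(seq_along(mc), function(k) {
        idx <- (offs[k] + 1L):offs[k + 1L]
        sc_w <- Filter(function(ct) ct$wall == walls[k], sc)
        if (!length(sc_w)) return(NA_real_)
        dice_metric(res$mapped[idx, , drop = FALSE], sc_w[[1L]])
      }, 0)
    }, error = function(e) rep(NA_real_, length(mc)))
    list(result = res, metrics = met, dm = dm,
         displacement = cbind(res$problem$M0, res$mapped))
  }

  slices <- lapply(zs, function(z) {
    sc <- scene[scene_z == z]
    mc <- model[abs(model_z - z) < 1e-9]
    if (!length(mc))
      return(list(z = z, error = "no model contour at this z level"))
    out <- list(z = z)
    if (cfg$direction %in% c("forward", "both")) {
      fw <- one_direction(sc, mc)
      out$forward <- list(apd = fw$metrics$apd_forward, dm = fw$dm,
                          cost_initial = fw$result$initial_cost,
                          cost_final = fw$result$final_cost,
                          converged = fw$result$converged)
      out$displacement <- fw$displacement
      out$theta <- fw$result$theta
    }
    if (cfg$direction %in% c("reverse", "both")) {
      rv <- one_direction(mc, sc)
      out$reverse <- list(apd = rv$metrics$apd_forward, dm = rv$dm,
                          cost_initial = rv$result$initial_cost,
                          cost_final = rv$result$final_cost,
                          converged = rv$result$converged)
    }
    out
  })

  apds <- unlist(lapply(slices, function(s)
    c(s$forward$apd, s$reverse$apd)))
  dms <- unlist(lapply(slices, function(s) c(s$forward$dm, s$reverse$dm)))
  dms <- dms[is.finite(dms)]
  result <- list(
    config = cfg[setdiff(names(cfg), c("scene", "model"))],
    defaults_used = list(sigma = ccfg$sigma %||% "0.1 x scene bbox diagonal",
                         beta = ccfg$beta, lambda = ccfg$lambda,
                         sgd = unclass(scfg)),
    slices = slices,
    summary = list(mean_apd = if (length(apds)) mean(apds) else NA_real_,
                   mean_dm = if (length(dms)) mean(dms) else NA_real_,
                   n_slices = length(slices)))
  if (!is.null(cfg$out))
    jsonlite::write_json(result, cfg$out, digits = NA, auto_unbox = TRUE,
                         force = TRUE)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
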