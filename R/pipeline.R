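#' Read a declarative pipeline recipe
#'
#' A recipe is a YAML file describing the section-by-section virion
#' workflow as data: an ordered list of steps, each naming an operation
#' (`qc`, `graft`, `stack`, `compose`, `interfaces`, `fitmap`, `symfit`),
#' its inputs (file paths, or `"@id"` references to the model produced by
#' an earlier step) and parameters, plus a `seed` and an `output`
#' directory. Shipped examples live under
#' `system.file("recipes", package = "phagebuilder")`.
#'
#' @param path YAML file path.
#' @return A list of class `recipe`.
#' @export
read_recipe <- function(path) {
  if (!file.exists(path)) stop("recipe file not found: ", path)
  r <- yaml::read_yaml(path)
  if (is.null(r$steps)) r$steps <- list()
  if (is.null(r$seed)) r$seed <- 1L
  if (is.null(r$output)) r$output <- "."
  r$source <- path
  class(r) <- "recipe"
  r
}

recipe_ops <- c("qc", "graft", "stack", "compose", "interfaces", "fitmap",
                "symfit")

#' Validate a recipe without running it
#'
#' @param recipe a [read_recipe] result (or an equivalent list).
#' @param base_dir directory against which relative input paths resolve.
#' @return character vector of problems; empty when valid.
#' @export
validate_recipe <- function(recipe, base_dir = ".") {
  problems <- character(0)
  steps <- recipe$steps
  if (!is.list(steps))
    return("`steps` is not a list")
  ids <- vapply(steps, function(s) s$id %||% "", character(1))
  if (any(ids == ""))
    problems <- c(problems, sprintf("step %d has no id",
                                    which(ids == "")[1]))
  if (anyDuplicated(ids[ids != ""]))
    problems <- c(problems, paste("duplicate step id:",
                                  ids[duplicated(ids)][1]))
  seen <- character(0)
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    op <- s$op %||% ""
    if (!op %in% recipe_ops)
      problems <- c(problems,
                    sprintf("step %s: unknown operation '%s'", ids[i], op))
    for (field in names(s)) {
      v <- s[[field]]
      if (is.character(v) && length(v) == 1L && startsWith(v, "@")) {
        ref <- substring(v, 2)
        if (!ref %in% seen)
          problems <- c(problems, sprintf(
            "step %s: reference '@%s' does not name an earlier step",
            ids[i], ref))
      } else if (is.character(v) && length(v) == 1L &&
                 field %in% c("model", "short_ring", "monomer", "tube",
                              "map", "pae")) {
        if (!file.exists(file.path(base_dir, v)))
          problems <- c(problems, sprintf("step %s: input file not found: %s",
                                          ids[i], v))
      }
    }
    seen <- c(seen, ids[i])
  }
  problems
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a recipe end to end
#'
#' Executes the steps in order under the recipe's seed, writing every model
#' artifact and a structured log into the output directory. A QC rejection
#' or a junction-gate failure halts the run with a machine-readable failure
#' record; all metrics (rmsd, buried areas, CC, verdicts) are aggregated
#' into one report.
#'
#' @param recipe a [read_recipe] result.
#' @param base_dir directory against which relative paths resolve,
#'   default the recipe's directory (or "." for in-memory recipes).
#' @return A list of class `run_report`: `success`, `steps` (per-step
#'   verdicts and metrics), `failure` (NULL or the failing step record),
#'   `artifacts`.
#' @export
run_recipe <- function(recipe, base_dir = NULL) {
  if (is.null(base_dir))
    base_dir <- if (!is.null(recipe$source)) dirname(recipe$source) else "."
  outdir <- file.path(base_dir, recipe$output)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(recipe$seed)
  problems <- validate_recipe(recipe, base_dir = base_dir)
  if (length(problems))
    stop("invalid recipe: ", paste(problems, collapse = "; "))
  models <- list()
  report <- list(success = TRUE, steps = list(), failure = NULL,
                 artifacts = character(0), seed = recipe$seed)
  logline <- character(0)
  resolve_model <- function(x, field, id) {
    if (inherits(x, "assembly_model")) return(x)
    if (is.character(x) && startsWith(x, "@")) {
      ref <- substring(x, 2)
      if (is.null(models[[ref]]))
        stop(sprintf("step %s: '@%s' produced no model", id, ref))
      return(models[[ref]])
    }
    read_structure(file.path(base_dir, x))
  }
  for (s in recipe$steps) {
    id <- s$id
    rec <- list(id = id, op = s$op, metrics = list())
    res <- tryCatch({
      switch(s$op,
        qc = {
          m <- resolve_model(s$model, "model", id)
          v <- accept_model(m, threshold = s$threshold %||% 70)
          rec$metrics$accepted <- v$accepted
          rec$metrics$folded_fraction_above_threshold <-
            v$folded_fraction_above_threshold
          if (!is.null(s$pae)) {
            pae <- read_pae(file.path(base_dir, s$pae), model = m)
            ids2 <- chain_ids(m)
            if (length(ids2) >= 2) {
              ip <- interchain_pae(pae, ids2[1], ids2[2])
              rec$metrics$interchain_pae_mean <- ip$mean
            }
          }
          if (!v$accepted)
            stop("QC rejection: model failed the confidence gate")
          models[[id]] <- m
          rec
        },
        graft = {
          g <- graft_full_length(resolve_model(s$short_ring, "short_ring", id),
                                 resolve_model(s$monomer, "monomer", id),
                                 shared_range = unlist(s$shared))
          rec$metrics$per_chain_rmsd <- g$graft$per_chain_rmsd
          rec$metrics$n_clashes <- g$graft$n_clashes
          models[[id]] <- g
          rec$artifact <- write_step_model(g, outdir, id)
          rec
        },
        stack = {
          t2 <- extend_stack(resolve_model(s$tube, "tube", id),
                             n_extra = s$add %||% 1L,
                             direction = s$direction %||% "top")
          rec$metrics$rise <- t2$stack$rise
          rec$metrics$twist <- t2$stack$twist
          models[[id]] <- t2
          rec$artifact <- write_step_model(t2, outdir, id)
          rec
        },
        compose = {
          parts <- lapply(s$parts, function(p) {
            list(model = resolve_model(p$model, "model", id),
                 junction = if (is.null(p$chains)) NULL else
                   list(chains = p$chains, onto = p$onto,
                        range = if (is.null(p$range)) NULL else unlist(p$range)))
          })
          cmp <- compose_assembly(parts, gate = s$gate %||% 5)
          rec$metrics$junction_rmsd <-
            vapply(cmp$junctions, function(j) j$rmsd, numeric(1))
          models[[id]] <- cmp
          rec$artifact <- write_step_model(cmp, outdir, id)
          rec
        },
        interfaces = {
          m <- resolve_model(s$model, "model", id)
          rep2 <- interface_report(m, n_points = s$n_points %||% 960L)
          rec$metrics$n_pairs <- nrow(rep2$pairs)
          rec$metrics$per_chain <- rep2$per_chain
          path <- file.path(outdir, paste0(id, "_interfaces.tsv"))
          write_interface_report(rep2, path)
          rec$artifact <- path
          rec
        },
        fitmap = {
          m <- resolve_model(s$model, "model", id)
          map <- read_map(file.path(base_dir, s$map),
                          resolution = s$resolution %||% NA_real_)
          f <- fit_in_map(m, map, resolution = s$resolution,
                          try_flip = isTRUE(s$try_flip))
          rec$metrics$cc <- f$cc
          rec$metrics$cc_global <- f$cc_global
          rec$metrics$flipped <- f$flipped
          models[[id]] <- f$model
          rec
        },
        symfit = {
          m <- resolve_model(s$model, "model", id)
          fit <- fit_cyclic_axis(m, order = s$order)
          rec$metrics$order <- fit$order
          rec$metrics$mean_rmsd <- fit$mean_rmsd
          rec$metrics$axis <- fit$axis_direction
          models[[id]] <- m
          rec
        })
    }, error = function(e) {
      structure(list(id = id, op = s$op,
                     error = conditionMessage(e)), class = "step_failure")
    })
    if (inherits(res, "step_failure")) {
      report$failure <- unclass(res)
      report$success <- FALSE
      report$steps[[id]] <- list(id = id, op = s$op, status = "failed",
                                 error = res$error)
      break
    }
    res$status <- "ok"
    report$steps[[id]] <- res
    if (!is.null(res$artifact))
      report$artifacts <- c(report$artifacts, res$artifact)
    logline <- c(logline, sprintf("[%s] %s ok", id, s$op))
  }
  log_path <- file.path(outdir, "run_log.json")
  jsonlite::write_json(report_to_json(report), log_path, auto_unbox = TRUE,
                       digits = 8, force = TRUE)
  report$artifacts <- c(report$artifacts, log_path)
  class(report) <- "run_report"
  report
}

write_step_model <- function(model, outdir, id) {
  path <- file.path(outdir, paste0(id, ".cif"))
  write_structure(model, path, format = "mmcif")
  path
}

report_to_json <- function(report) {
  steps <- lapply(report$steps, function(s) {
    s$metrics <- lapply(s$metrics, function(m)
      if (is.data.frame(m)) as.list(m) else m)
    s
  })
  list(success = report$success, seed = report$seed, steps = steps,
       failure = report$failure)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %s, %d step(s)\n",
              if (x$success) "SUCCESS" else "FAILED", length(x$steps)))
  for (s in x$steps) {
    cat(sprintf("  [%s] %s: %s\n", s$id, s$op, s$status))
    if (!is.null(s$error)) cat("    error:", s$error, "\n")
  }
  invisible(x)
}
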