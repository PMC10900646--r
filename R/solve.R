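#' Solve an ILP model with an external MIP backend
#'
#' Two open backends are supported: `"glpk"` runs the `glpsol` command-line
#' solver on a CPLEX-LP export of the model; `"scipy"` solves through the
#' HiGHS branch-and-bound behind `scipy.optimize.milp`, via the `python`
#' interpreter. `"auto"` picks `glpsol` when it is on the `PATH` and falls
#' back to scipy.
#'
#' @param model An [build_model()] result.
#' @param time_limit Solver time limit in seconds.
#' @param solver `"auto"`, `"glpk"` or `"scipy"`.
#' @return Object of class `ilp_solution`: `status` (`"optimal"` or
#'   `"feasible"`), `objective`, `bound` (best proven lower bound; equals
#'   the objective at optimality), and `x` (named variable assignment).
#' @export
solve_ilp <- function(model, time_limit = 60, solver = "auto") {
  solver <- resolve_solver(solver)
  if (solver == "glpk") solve_glpk(model, time_limit)
  else solve_scipy_batch(list(model), time_limit)[[1]]
}

resolve_solver <- function(solver) {
  solver <- match.arg(solver, c("auto", "glpk", "scipy"))
  if (solver == "auto") {
    if (nzchar(Sys.which("glpsol"))) "glpk"
    else if (nzchar(Sys.which("python")) || nzchar(Sys.which("python3"))) "scipy"
    else stop("no MIP backend available (need glpsol or python+scipy)")
  } else solver
}

solve_glpk <- function(model, time_limit) {
  lp <- tempfile(fileext = ".lp"); sol <- tempfile(fileext = ".sol")
  on.exit(unlink(c(lp, sol)), add = TRUE)
  write_lp(model, lp)
  out <- suppressWarnings(system2(
    "glpsol", c("--lp", shQuote(lp), "-o", shQuote(sol),
                "--tmlim", as.character(max(1L, as.integer(ceiling(time_limit))))),
    stdout = TRUE, stderr = TRUE))
  if (!file.exists(sol))
    stop("glpsol produced no solution file; output was:\n",
         paste(utils::tail(out, 5), collapse = "\n"))
  lines <- readLines(sol, warn = FALSE)
  status_line <- grep("^Status:", lines, value = TRUE)[1]
  status <- if (grepl("INTEGER OPTIMAL", status_line)) "optimal"
    else if (grepl("INTEGER NON-OPTIMAL", status_line)) "feasible"
    else stop("glpk solve failed: ", status_line)
  obj_line <- grep("^Objective:", lines, value = TRUE)[1]
  objective <- as.numeric(sub(".*=\\s*([-0-9.eE+]+)\\s*\\(.*", "\\1", obj_line))
  # column table: "   No. Column name  Activity ..." with a '*' marker on
  # integer columns; names are short so rows never wrap
  col_head <- grep("Column name", lines)[1]
  x <- numeric(nrow(model$vars))
  names(x) <- model$vars$name
  for (ln in lines[seq.int(col_head + 2L, length(lines))]) {
    if (!grepl("^\\s*[0-9]+\\s", ln)) break
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    nm <- toks[2]
    act <- toks[if (identical(toks[3], "*")) 4L else 3L]
    if (nm %in% names(x)) x[nm] <- as.numeric(act)
  }
  structure(list(status = status, objective = objective,
                 bound = if (status == "optimal") objective else NA_real_,
                 x = x, solver = "glpk"),
            class = "ilp_solution")
}

model_to_json_list <- function(model) {
  rows <- model$rows
  list(
    obj = model$vars$obj,
    lb = model$vars$lb, ub = model$vars$ub,
    integer = as.integer(model$vars$type %in% c("I", "B")),
    con_row = unlist(lapply(seq_along(rows), function(i)
      rep(i - 1L, length(rows[[i]]$idx)))),
    con_col = unlist(lapply(rows, function(r) r$idx - 1L)),
    con_coef = unlist(lapply(rows, function(r) r$coef)),
    row_sense = vapply(rows, function(r) r$sense, character(1)),
    row_rhs = vapply(rows, function(r) r$rhs, numeric(1)))
}

#' Solve several ILP models in one scipy/HiGHS process
#'
#' Amortizes interpreter start-up when many small models are solved, as in
#' the simulation studies.
#'
#' @param models List of [build_model()] results.
#' @param time_limit Per-model time limit in seconds.
#' @return List of `ilp_solution` objects.
#' @export
solve_scipy_batch <- function(models, time_limit = 60) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("python interpreter not found")
  script <- system.file("python", "milp_solve.py", package = "dcjindel")
  if (!nzchar(script)) script <- file.path("inst", "python", "milp_solve.py")
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  payload <- list(time_limit = time_limit,
                  models = lapply(models, model_to_json_list))
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  out <- suppressWarnings(system2(py, c(shQuote(script), shQuote(fin),
                                        shQuote(fout)),
                                  stdout = TRUE, stderr = TRUE))
  if (!file.exists(fout))
    stop("scipy backend failed:\n", paste(utils::tail(out, 10), collapse = "\n"))
  res <- jsonlite::read_json(fout, simplifyVector = TRUE)
  lapply(seq_along(models), function(i) {
    r <- if (is.data.frame(res)) res[i, ] else res[[i]]
    x <- as.numeric(unlist(r$x))
    names(x) <- models[[i]]$vars$name
    structure(list(status = as.character(r$status),
                   objective = as.numeric(r$objective),
                   bound = as.numeric(r$bound), x = x, solver = "scipy"),
              class = "ilp_solution")
  })
}

#' @export
print.ilp_solution <- function(x, ...) {
  cat("ILP solution:", x$status, " objective =", x$objective,
      " bound =", x$bound, " (", x$solver, ")\n")
  invisible(x)
}

#' Extract matching, report and distance from an ILP solution
#'
#' The matching is read off the selected extremity-edge sibling pairs; the
#' component report and distance are then *recomputed* from the
#' decomposition with [resolved_distance()] rather than trusted from the
#' solver's report variables (benign over-reporting is legal in feasible
#' assignments). At optimality the recomputed distance equals the solver
#' objective.
#'
#' @param m The augmented MRD the model was built from.
#' @param model The [build_model()] result.
#' @param sol An [solve_ilp()] result.
#' @return List with `matching` ([resolved_matching()]), `report`
#'   ([component_report()]) and `distance`.
#' @export
extract_solution <- function(m, model, sol) {
  sel <- sol$x[model$meta$pair_rep] > 0.5
  occ_a <- model$meta$pair_occ[sel, 1]
  occ_b <- model$meta$pair_occ[sel, 2]
  if (anyDuplicated(occ_a) || anyDuplicated(occ_b))
    stop("inconsistent x assignment: matching is not injective")
  matching <- resolved_matching(occ_a, occ_b, m$fams)
  rd <- resolved_distance(m$a, m$b, matching)
  if (sol$status == "optimal" && rd$distance != round(sol$objective))
    warning("recomputed distance ", rd$distance,
            " differs from solver objective ", sol$objective)
  list(matching = matching, report = rd$report, distance = rd$distance)
}

#' DCJ-indel distance of natural genomes via the capping-free ILP
#'
#' End-to-end pipeline: derive families, build and augment the MRD, build
#' the capping-free ILP for the chosen matching model, solve it, and
#' recompute matching, component report and distance from the solution.
#'
#' @param a,b `dcj_genome` objects with occurrence ids assigned.
#' @param model Matching model (`"maximum"`, `"intermediate"`,
#'   `"exemplar"`).
#' @param solver,time_limit Passed to [solve_ilp()].
#' @param export_lp,export_mps Optional paths for model export.
#' @return List with `distance`, `matching`, `report`, `solution` (the raw
#'   `ilp_solution`), and `model`.
#' @examples
#' \donttest{
#' gs <- parse_unimog(">A\n1 1 2 |\n>B\n1 2 |")
#' res <- dcj_indel_ilp(gs[[1]], gs[[2]])
#' res$distance
#' }
#' @export
dcj_indel_ilp <- function(a, b, model = "maximum", solver = "auto",
                          time_limit = 60, export_lp = NULL,
                          export_mps = NULL) {
  fams <- derive_families(a, b)
  mrd <- augment_mrd(build_mrd(a, b, fams))
  bounds <- family_bounds(fams, model)
  ilp <- build_model(mrd, bounds)
  if (!is.null(export_lp)) write_lp(ilp, export_lp)
  if (!is.null(export_mps)) write_mps(ilp, export_mps)
  sol <- solve_ilp(ilp, time_limit = time_limit, solver = solver)
  ext <- extract_solution(mrd, ilp, sol)
  c(ext, list(solution = sol, model = ilp))
}
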