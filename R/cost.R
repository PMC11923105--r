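#' Construct a workflow cost model
#'
#' @param name Workflow name.
#' @param components data.frame with columns `component`, `basis`
#'   (`per_sample`, `per_plate` or `per_pool`) and `unit_cost`.
#' @param wellsPerPlate Wells per plate for amortizing per-plate costs
#'   (default 96).
#' @return A [WorkflowCostModel-class].
#' @export
workflowModel <- function(name, components, wellsPerPlate = 96L) {
  new("WorkflowCostModel", name = name,
      components = as.data.frame(components),
      wellsPerPlate = as.integer(wellsPerPlate))
}

setMethod("show", "WorkflowCostModel", function(object) {
  cat(sprintf("WorkflowCostModel '%s' (%d components, %d wells/plate)\n",
              object@name, nrow(object@components), object@wellsPerPlate))
  print(object@components, row.names = FALSE)
})

#' Per-colony cost of a workflow
#'
#' Per-sample components accrue once per colony; per-plate components are
#' amortized over the colonies via the number of plates needed
#' (`ceiling(n / wellsPerPlate)`); per-pool components (e.g. one bead
#' purification of the pooled library, one sequencing run) are split over
#' all `n` colonies. Cost per colony is therefore non-increasing in `n`.
#'
#' @param model A [WorkflowCostModel-class].
#' @param nColonies Number of colonies genotyped (>= 1).
#' @return list with `total` (per-colony cost) and `breakdown`
#'   (data.frame component, basis, per_colony; sums to `total`).
#' @export
perColonyCost <- function(model, nColonies) {
  if (nColonies < 1L) stop("parameter error: nColonies must be >= 1")
  cmp <- model@components
  plates <- ceiling(nColonies / model@wellsPerPlate)
  perColony <- ifelse(cmp$basis == "per_sample", cmp$unit_cost,
               ifelse(cmp$basis == "per_plate",
                      cmp$unit_cost * plates / nColonies,
                      cmp$unit_cost / nColonies))
  breakdown <- data.frame(component = cmp$component, basis = cmp$basis,
                          per_colony = perColony)
  list(total = sum(perColony), breakdown = breakdown)
}

#' Compare workflows at a given scale
#'
#' @param models List of [WorkflowCostModel-class] objects (>= 2).
#' @param nColonies Number of colonies.
#' @return data.frame with one row per workflow — `workflow`,
#'   `per_colony_total`, then one column per component — sorted by
#'   ascending total (ties broken by name).
#' @export
compareWorkflows <- function(models, nColonies) {
  if (length(models) < 2L) stop("need at least two models to compare")
  rows <- lapply(models, function(m) {
    pc <- perColonyCost(m, nColonies)
    comp <- stats::setNames(pc$breakdown$per_colony,
                            pc$breakdown$component)
    c(list(workflow = m@name, per_colony_total = pc$total), as.list(comp))
  })
  allCols <- unique(unlist(lapply(rows, names)))
  tab <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(allCols, names(r))
    r[miss] <- 0
    as.data.frame(r[allCols], check.names = FALSE)
  }))
  tab <- tab[order(tab$per_colony_total, tab$workflow), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Load workflow cost models from a YAML config
#'
#' Expected structure:
#' ```
#' wells_per_plate: 96
#' workflows:
#'   <name>:
#'     components:
#'       - {name: ..., basis: per_sample|per_plate|per_pool, unit_cost: ...}
#' ```
#'
#' @param file YAML path; default the packaged example config (placeholder
#'   prices — edit for your reagents and facility).
#' @return Named list of [WorkflowCostModel-class] objects.
#' @export
readCostConfig <- function(file = system.file("extdata",
                                              "cost_defaults.yaml",
                                              package = "platemux")) {
  cfg <- yaml::read_yaml(file)
  wpp <- if (is.null(cfg$wells_per_plate)) 96L else cfg$wells_per_plate
  models <- lapply(names(cfg$workflows), function(nm) {
    comps <- do.call(rbind, lapply(cfg$workflows[[nm]]$components,
      function(x) data.frame(component = x$name, basis = x$basis,
                             unit_cost = x$unit_cost)))
    workflowModel(nm, comps, wpp)
  })
  stats::setNames(models, names(cfg$workflows))
}
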