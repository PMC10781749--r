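#' Define a system-model component
#'
#' A component is one gene family of a multi-gene system (e.g. TssB or
#' TssN), with a status deciding how it enters the quorum rule:
#' `mandatory` components count towards the minimum-mandatory quorum,
#' `accessory` components only towards the total-distinct quorum.
#'
#' @param name Single non-empty character, the component identifier.
#' @param status Either `"mandatory"` or `"accessory"`.
#' @return A one-row data frame with columns `name` and `status`.
#' @export
component_def <- function(name, status = c("accessory", "mandatory")) {
  status <- match.arg(status)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("component 'name' must be a single non-empty string", call. = FALSE)
  data.frame(name = name, status = status, stringsAsFactors = FALSE)
}

#' Construct and validate a system model
#'
#' A system model declares the components of a multi-gene system, which
#' of them are mandatory, and the co-localization rule used to call the
#' system present in a genome: at least `min_mandatory` distinct
#' mandatory components and `min_total` distinct components overall must
#' be found, in gene clusters whose consecutive component genes are
#' separated by at most `inter_gene_max_distance` intervening genes.
#' With `multi_loci = TRUE` the clusters of one genome are pooled before
#' the quorum is evaluated, accommodating systems encoded in several
#' loci scattered in the genome.
#'
#' @param name Model label.
#' @param components Data frame with columns `name` and `status`
#'   (typically built by rbinding [component_def()] rows).
#' @param min_mandatory Minimum number of distinct mandatory components.
#' @param min_total Minimum number of distinct components overall.
#' @param inter_gene_max_distance Maximum number of intervening genes
#'   allowed between consecutive component genes of one cluster.
#' @param multi_loci Logical; pool all clusters of a genome before
#'   evaluating the quorum.
#' @return An object of class `system_model`.
#' @examples
#' m <- system_model(
#'   "toy",
#'   rbind(component_def("TssB"), component_def("TssN", "mandatory")),
#'   min_mandatory = 1, min_total = 2
#' )
#' @export
system_model <- function(name, components, min_mandatory, min_total,
                         inter_gene_max_distance = 10, multi_loci = TRUE) {
  stopifnot(is.data.frame(components),
            all(c("name", "status") %in% names(components)))
  components$name <- as.character(components$name)
  components$status <- as.character(components$status)
  if (anyDuplicated(components$name))
    stop("duplicate component names in model '", name, "'", call. = FALSE)
  if (any(!nzchar(components$name)))
    stop("empty component name in model '", name, "'", call. = FALSE)
  bad <- setdiff(unique(components$status), c("mandatory", "accessory"))
  if (length(bad))
    stop("invalid component status: ", paste(bad, collapse = ", "),
         " (must be 'mandatory' or 'accessory')", call. = FALSE)
  min_mandatory <- as.integer(min_mandatory)
  min_total <- as.integer(min_total)
  n_mand <- sum(components$status == "mandatory")
  if (min_mandatory > n_mand)
    stop("min_mandatory (", min_mandatory, ") exceeds the number of ",
         "mandatory components (", n_mand, ")", call. = FALSE)
  if (min_mandatory > min_total)
    stop("min_mandatory exceeds min_total", call. = FALSE)
  if (min_total > nrow(components))
    stop("min_total (", min_total, ") exceeds the number of distinct ",
         "components (", nrow(components), ")", call. = FALSE)
  if (inter_gene_max_distance < 0)
    stop("inter_gene_max_distance must be >= 0", call. = FALSE)
  structure(
    list(name = as.character(name),
         components = components[, c("name", "status")],
         min_mandatory = min_mandatory,
         min_total = min_total,
         inter_gene_max_distance = as.integer(inter_gene_max_distance),
         multi_loci = isTRUE(multi_loci)),
    class = "system_model")
}

#' @export
print.system_model <- function(x, ...) {
  cat("System model '", x$name, "': ", nrow(x$components), " components (",
      sum(x$components$status == "mandatory"), " mandatory)\n", sep = "")
  cat("  quorum: >=", x$min_mandatory, "mandatory, >=", x$min_total,
      "distinct overall; d_max =", x$inter_gene_max_distance,
      if (x$multi_loci) "; multi-loci pooling on" else "", "\n")
  invisible(x)
}

#' Mandatory component names of a model
#' @param model A `system_model`.
#' @return Character vector.
#' @export
mandatory_components <- function(model) {
  stopifnot(inherits(model, "system_model"))
  model$components$name[model$components$status == "mandatory"]
}

#' Load a system model from a YAML configuration file
#'
#' The document must declare `name`, `components` (a mapping of
#' component name to status), `min_mandatory`, `min_total`,
#' `inter_gene_max_distance` and `multi_loci`. Missing fields raise a
#' configuration error naming the field; invariant violations raise a
#' validation error via [system_model()].
#'
#' @param path Path to the YAML document.
#' @return A validated `system_model`.
#' @seealso [write_system_model()] for the inverse; the two round-trip.
#' @export
load_system_model <- function(path) {
  if (!file.exists(path))
    stop("model file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  required <- c("name", "components", "min_mandatory", "min_total",
                "inter_gene_max_distance", "multi_loci")
  missing <- setdiff(required, names(doc))
  if (length(missing))
    stop("model configuration is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  comps <- data.frame(name = names(doc$components),
                      status = unlist(doc$components, use.names = FALSE),
                      stringsAsFactors = FALSE)
  system_model(doc$name, comps,
               min_mandatory = doc$min_mandatory,
               min_total = doc$min_total,
               inter_gene_max_distance = doc$inter_gene_max_distance,
               multi_loci = doc$multi_loci)
}

#' Write a system model as YAML
#' @param model A `system_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_system_model <- function(model, path) {
  stopifnot(inherits(model, "system_model"))
  comps <- as.list(stats::setNames(model$components$status,
                                   model$components$name))
  yaml::write_yaml(
    list(name = model$name,
         components = comps,
         min_mandatory = model$min_mandatory,
         min_total = model$min_total,
         inter_gene_max_distance = model$inter_gene_max_distance,
         multi_loci = model$multi_loci),
    path)
  invisible(path)
}

#' The T6SS-iii detection models
#'
#' Two ready-made models for the Bacteroidota-specific type VI secretion
#' system. `t6ss_iii_model()` is the full membrane-complex-anchored
#' model: nine universal components (TssB, TssC, TssD, TssE, TssF, TssG,
#' TssH, TssI, TssK) as accessory plus the five membrane-complex (MC)
#' components TssN, TssO, TssP, TssQ, TssR as mandatory, with a quorum
#' of 1 mandatory and 8 distinct genes overall, a maximum inter-gene
#' distance of 10 and multi-locus pooling. `t6ss_universal_model()`
#' searches the universal components only (all mandatory, quorum 6/6),
#' used to look for T6SS loci independently of the MC.
#'
#' @return A `system_model`.
#' @export
t6ss_iii_model <- function() {
  universal <- c("TssB", "TssC", "TssD", "TssE", "TssF", "TssG", "TssH",
                 "TssI", "TssK")
  mc <- c("TssN", "TssO", "TssP", "TssQ", "TssR")
  comps <- data.frame(
    name = c(universal, mc),
    status = c(rep("accessory", length(universal)),
               rep("mandatory", length(mc))),
    stringsAsFactors = FALSE)
  system_model("T6SSiii", comps, min_mandatory = 1, min_total = 8,
               inter_gene_max_distance = 10, multi_loci = TRUE)
}

#' @rdname t6ss_iii_model
#' @export
t6ss_universal_model <- function() {
  universal <- c("TssB", "TssC", "TssD", "TssE", "TssF", "TssG", "TssH",
                 "TssI", "TssK")
  comps <- data.frame(name = universal, status = "mandatory",
                      stringsAsFactors = FALSE)
  system_model("T6SS-universal", comps, min_mandatory = 6, min_total = 6,
               inter_gene_max_distance = 10, multi_loci = TRUE)
}

#' Membrane-complex component names
#' @return Character vector of the five MC components.
#' @export
mc_components <- function() c("TssN", "TssO", "TssP", "TssQ", "TssR")
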