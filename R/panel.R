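#' Construct a FISH probe panel
#'
#' A probe panel is an ordered set of locus-specific FISH probes. Each probe
#' is either a gene probe (scored against the nucleus ploidy for gains and
#' losses) or a centromere reference probe (used to anchor the ploidy
#' annotation). Gene probes additionally carry a gene class so that exports
#' can distinguish oncogenes from tumor suppressors.
#'
#' @param name character vector of unique probe names.
#' @param locus cytoband labels, same length as `name`.
#' @param role `"gene"` or `"centromere"` per probe.
#' @param gene_class `"oncogene"`, `"tumor_suppressor"` or `"none"` per probe;
#'   centromere probes must be `"none"`.
#' @return A `probe_panel` object: a data.frame with columns `name`, `locus`,
#'   `role`, `gene_class`, one row per probe in scoring order.
#' @examples
#' panel <- default_panel()
#' gene_probes(panel)
#' @export
probe_panel <- function(name, locus, role, gene_class = NULL) {
  if (is.null(gene_class)) gene_class <- rep("none", length(name))
  stopifnot(length(locus) == length(name), length(role) == length(name),
            length(gene_class) == length(name))
  if (anyDuplicated(name)) stop("probe names must be unique")
  if (!all(role %in% c("gene", "centromere")))
    stop("role must be 'gene' or 'centromere'")
  if (!all(gene_class %in% c("oncogene", "tumor_suppressor", "none")))
    stop("gene_class must be 'oncogene', 'tumor_suppressor' or 'none'")
  if (!any(role == "gene")) stop("panel needs at least one gene probe")
  if (any(role == "centromere" & gene_class != "none"))
    stop("centromere probes cannot carry a gene_class")
  panel <- data.frame(name = as.character(name), locus = as.character(locus),
                      role = role, gene_class = gene_class,
                      stringsAsFactors = FALSE)
  class(panel) <- c("probe_panel", "data.frame")
  panel
}

#' Default breast-cancer miFISH panel
#'
#' Eight breast-cancer-related gene probes plus two centromere reference
#' probes (CCP4, CCP10), in scoring order.
#'
#' @return A [probe_panel()] with 10 probes.
#' @export
default_panel <- function() {
  probe_panel(
    name = c("COX2", "DBC2", "MYC", "CCND1", "CDH1", "TP53", "HER2", "ZNF217",
             "CCP4", "CCP10"),
    locus = c("1q31.1", "8p21.3", "8q24.21", "11q13.3", "16q22.1", "17p13.1",
              "17q12", "20q13.2", "cen4", "cen10"),
    role = c(rep("gene", 8), rep("centromere", 2)),
    gene_class = c("oncogene", "tumor_suppressor", "oncogene", "oncogene",
                   "tumor_suppressor", "tumor_suppressor", "oncogene",
                   "oncogene", "none", "none")
  )
}

#' @export
print.probe_panel <- function(x, ...) {
  cat(sprintf("<probe_panel> %d probes (%d gene, %d centromere)\n",
              nrow(x), sum(x$role == "gene"), sum(x$role == "centromere")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Names of the gene probes of a panel, in panel order
#' @param panel a [probe_panel()].
#' @return character vector.
#' @export
gene_probes <- function(panel) panel$name[panel$role == "gene"]

#' Names of the centromere probes of a panel, in panel order
#' @param panel a [probe_panel()].
#' @return character vector (possibly empty).
#' @export
centromere_probes <- function(panel) panel$name[panel$role == "centromere"]

#' Read a probe panel from a YAML or JSON file
#'
#' The file holds a list of probe descriptors with fields `name`, `locus`,
#' `role` and `gene_class` (either a top-level list or under a `probes` key).
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` vs
#'   `.json`).
#' @return A [probe_panel()].
#' @export
read_panel <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    yaml::yaml.load(paste(readLines(path, warn = FALSE), collapse = "\n"))
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$probes)) raw <- raw$probes
  probe_panel(
    name = vapply(raw, `[[`, character(1), "name"),
    locus = vapply(raw, `[[`, character(1), "locus"),
    role = vapply(raw, `[[`, character(1), "role"),
    gene_class = vapply(raw, function(p) {
      gc <- p$gene_class
      if (is.null(gc)) "none" else gc
    }, character(1))
  )
}

#' Write a probe panel to YAML
#' @param panel a [probe_panel()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  probes <- lapply(seq_len(nrow(panel)), function(i) {
    list(name = panel$name[i], locus = panel$locus[i], role = panel$role[i],
         gene_class = panel$gene_class[i])
  })
  yaml::write_yaml(list(probes = probes), path)
  invisible(path)
}
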