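# Parcellation tables: region labels + canonical resting-state network
# assignment, shared (positionally) by every connectivity matrix in a run.

#' Canonical resting-state network names
#'
#' The seven cortical networks of the widely used 7-network taxonomy
#' (visual, somatomotor, limbic, dorsal attention, ventral attention,
#' default mode, frontoparietal) plus a `subcortical` bucket for deep
#' grey-matter regions appended to cortical atlases.
#'
#' @format Character vector of length 8.
#' @export
RSN_NETWORKS <- c(
  "visual", "somatomotor", "limbic", "dorsal_attention",
  "ventral_attention", "default_mode", "frontoparietal", "subcortical"
)

#' Construct a parcellation
#'
#' A parcellation is an ordered table of brain regions, each assigned to one
#' of the canonical resting-state networks (see [RSN_NETWORKS]). Region order
#' is positional and must match the row/column order of every connectivity
#' matrix analysed with it.
#'
#' @param labels Character vector of unique region labels.
#' @param networks Character vector (same length) of network assignments,
#'   each one of [RSN_NETWORKS].
#' @param name Optional name for the parcellation (e.g. the atlas it mimics).
#' @return A `parcellation` object: a data.frame with columns `label` and
#'   `network` and attribute `name`.
#' @export
parcellation <- function(labels, networks, name = "unnamed") {
  labels <- as.character(labels)
  networks <- as.character(networks)
  if (length(labels) != length(networks)) {
    stop("`labels` and `networks` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate region labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(networks), RSN_NETWORKS)
  if (length(bad) > 0) {
    stop("unknown network name(s): ", paste(bad, collapse = ", "),
         "; allowed names are: ", paste(RSN_NETWORKS, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(label = labels, network = networks,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("parcellation", "data.frame")
  out
}

#' Read a parcellation table from TSV
#'
#' Expects a tab-separated file with a header row containing at least the
#' columns `label` and `network`. Lines starting with `#` are ignored.
#'
#' @param path Path to the TSV file.
#' @param name Name for the parcellation; defaults to the file name.
#' @return A [parcellation] object.
#' @export
read_parcellation <- function(path, name = basename(path)) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("label", "network") %in% names(df))) {
    stop("parcellation file must have columns `label` and `network`: ", path,
         call. = FALSE)
  }
  parcellation(df$label, df$network, name = name)
}

#' Write a parcellation table to TSV
#'
#' @param parc A [parcellation] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(parc, path) {
  stopifnot(inherits(parc, "parcellation"))
  utils::write.table(as.data.frame(parc)[, c("label", "network")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Number of regions in a parcellation
#' @param parc A [parcellation] object.
#' @return Integer region count.
#' @export
n_regions <- function(parc) nrow(parc)

#' Indices of the regions belonging to one network
#' @param parc A [parcellation] object.
#' @param network One of [RSN_NETWORKS].
#' @return Integer vector of region indices (possibly empty).
#' @export
network_members <- function(parc, network) {
  network <- match.arg(network, RSN_NETWORKS)
  which(parc$network == network)
}

#' @export
print.parcellation <- function(x, ...) {
  cat("Parcellation '", attr(x, "name"), "': ", nrow(x), " regions\n",
      sep = "")
  print(table(x$network), ...)
  invisible(x)
}

#' Generate a synthetic parcellation
#'
#' Distributes `n` regions over the seven cortical networks roughly evenly
#' (largest networks get the remainder) plus an optional subcortical block.
#' Useful for simulations at region counts where no packaged fixture exists.
#'
#' @param n Total number of regions (>= 8).
#' @param n_subcortical Number of regions labelled `subcortical`.
#' @param seed Unused (assignment is deterministic); kept for interface
#'   stability.
#' @return A [parcellation] object named `"synthetic"`.
#' @export
synthetic_parcellation <- function(n, n_subcortical = min(14L, n %/% 8L),
                                   seed = NULL) {
  stopifnot(n >= 8, n_subcortical >= 0, n_subcortical < n)
  cortical_nets <- setdiff(RSN_NETWORKS, "subcortical")
  n_cort <- n - n_subcortical
  base <- n_cort %/% length(cortical_nets)
  extra <- n_cort %% length(cortical_nets)
  sizes <- rep(base, length(cortical_nets)) +
    c(rep(1L, extra), rep(0L, length(cortical_nets) - extra))
  networks <- c(rep(cortical_nets, times = sizes),
                rep("subcortical", n_subcortical))
  counts <- stats::ave(seq_along(networks), networks, FUN = seq_along)
  labels <- paste0(networks, "_", counts)
  parcellation(labels, networks, name = "synthetic")
}
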