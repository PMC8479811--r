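#' Tidy a match solution into a tibble
#'
#' One row per atom tuple of the solution, with the matched atom name (or
#' `"DUM"`) in each state and a per-tuple perturbation status mirroring the
#' usual colouring of perturbation diagrams: `"unperturbed"` (all parameters
#' equal), `"perturbed"` (matched but with parameter changes) or `"dummy"`
#' (absent in at least one state).
#'
#' @param x A `match_solution`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.match_solution <- function(x, ...) {
  mat <- x$matches
  ns <- ncol(mat)
  labels <- vapply(x$states, function(s) s$title, character(1))
  out <- tibble::tibble(tuple = seq_len(nrow(mat)))
  for (s in seq_len(ns)) {
    nm <- ifelse(is.na(mat[, s]), "DUM",
                 x$states[[s]]$atoms$name[ifelse(is.na(mat[, s]), 1L, mat[, s])])
    out[[paste0("state", s, "_atom")]] <- nm
  }
  status <- rep("unperturbed", nrow(mat))
  status[rowSums(is.na(mat)) > 0L] <- "dummy"
  pert_atoms <- unique(unlist(strsplit(
    x$perturbed_terms$atoms[x$perturbed_terms$category %in%
                              c("atom_type", "mass", "charge")], ",")))
  for (s in seq_len(ns)) {
    nm <- out[[paste0("state", s, "_atom")]]
    status[status == "unperturbed" & nm %in% pert_atoms] <- "perturbed"
  }
  out$status <- status
  out
}

#' One-row summary of a match solution
#'
#' @param x A `match_solution`.
#' @param ... Unused.
#' @return A tibble with the match size, dummy count, score total and the
#'   per-category penalty counts.
#' @export
glance.match_solution <- function(x, ...) {
  bd <- as.list(x$score$breakdown)
  names(bd) <- paste0("n_", names(bd))
  tibble::as_tibble(c(list(
    n_states = ncol(x$matches),
    n_tuples = nrow(x$matches),
    n_matched = sum(rowSums(!is.na(x$matches)) >= 2L),
    n_dummy_entries = sum(is.na(x$matches)),
    score_total = x$score$total), bd))
}

#' Tidy a perturbation topology
#'
#' @param x A `pert_topology`.
#' @param ... Unused.
#' @return The union atom tibble with per-state parameters, dummy flags and
#'   a `status` column (unperturbed / perturbed / dummy_A / dummy_B).
#' @export
tidy.pert_topology <- function(x, ...) {
  at <- x$atoms
  status <- ifelse(at$dummy_a, "dummy_A",
                   ifelse(at$dummy_b, "dummy_B",
                          ifelse(at$type_a == at$type_b &
                                   charges_equal(at$charge_a, at$charge_b) &
                                   masses_equal(at$mass_a, at$mass_b),
                                 "unperturbed", "perturbed")))
  dplyr::mutate(at, status = status)
}

#' One-row summary of a perturbation topology
#'
#' @param x A `pert_topology`.
#' @param ... Unused.
#' @return A tibble with atom/dummy/perturbed counts and per-state total
#'   charges.
#' @export
glance.pert_topology <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_atoms = nrow(td),
    n_dummy_a = sum(td$dummy_a), n_dummy_b = sum(td$dummy_b),
    n_perturbed = sum(td$status == "perturbed"),
    n_unperturbed = sum(td$status == "unperturbed"),
    charge_a = sum(td$charge_a), charge_b = sum(td$charge_b),
    state_a = x$state_labels[1], state_b = x$state_labels[2])
}

pert_plot_data <- function(obj) {
  at <- tidy(obj)
  g <- igraph::graph_from_edgelist(as.matrix(obj$bonds[, c("i", "j")]),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nrow(at) - igraph::vcount(g)))
  # deterministic layout (no RNG involvement)
  xy <- igraph::layout_with_kk(g, coords = igraph::layout_in_circle(g))
  at$x <- xy[, 1]; at$y <- xy[, 2]
  seg <- tibble::tibble(
    x = at$x[obj$bonds$i], y = at$y[obj$bonds$i],
    xend = at$x[obj$bonds$j], yend = at$y[obj$bonds$j])
  list(atoms = at, bonds = seg)
}

#' Plot a perturbation topology
#'
#' Draws the union molecule with the conventional colouring: unperturbed
#' atoms blue, perturbed atoms red, dummy atoms grey.
#'
#' @param object A `pert_topology`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pert_topology <- function(object, ...) {
  pd <- pert_plot_data(object)
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = pd$bonds,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = pd$atoms,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$status), size = 6) +
    ggplot2::geom_text(data = pd$atoms,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_colour_manual(values = c(
      unperturbed = "#3366cc", perturbed = "#cc3333",
      dummy_A = "grey45", dummy_B = "grey70")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL,
                  title = sprintf("%s -> %s", object$state_labels[1],
                                  object$state_labels[2]))
}

#' Plot a match solution
#'
#' @param object A `match_solution` (pairwise solutions are rendered through
#'   their perturbation topology).
#' @param ... Passed on.
#' @return A ggplot object.
#' @export
autoplot.match_solution <- function(object, ...) {
  autoplot(build_pert_topology(object, 1L, 2L), ...)
}
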