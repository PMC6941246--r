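# The app registry: a declarative table tying model specs, backends, and
# descriptive text together -- the scriptable analogue of a simulation-app
# menu. Adding a model means writing one model_spec constructor and one
# entry here; the engines need no changes.

app_table <- function() {
  list(
    basicbacteria = list(
      id = "basicbacteria",
      title = "Basic bacteria and immune response model",
      description = paste("Logistic bacterial growth with mass-action",
                          "immune activation (r*B*I) and immune decay"),
      spec_fn = make_basic_bacteria_model,
      backends = c("ode", "discrete", "stochastic"),
      references = c("predator-prey-type within-host dynamics")),
    basicbacteria_saturated = list(
      id = "basicbacteria_saturated",
      title = "Bacteria model with saturating immune activation",
      description = paste("As basicbacteria, but immune activation",
                          "saturates at high load: r*B*I/(s + B)"),
      spec_fn = make_saturated_immunity_model,
      backends = c("ode", "discrete", "stochastic"),
      references = c("Michaelis-Menten-type saturating activation")))
}

#' Look up a registered simulation app
#'
#' @param id App id string.
#' @return The registry entry: a list with `id`, `title`, `description`,
#'   `spec` (the instantiated [model_spec()]), `backends`, `references`.
#' @examples
#' get_app("basicbacteria")$backends
#' @export
get_app <- function(id) {
  tbl <- app_table()
  if (!id %in% names(tbl))
    stop("unknown app '", id, "'; known apps: ",
         paste(names(tbl), collapse = ", "))
  entry <- tbl[[id]]
  entry$spec <- entry$spec_fn()
  entry
}

#' List all registered simulation apps
#'
#' @return A data frame with one row per app (stable order): id, title,
#'   description, and the available backend ids.
#' @export
list_apps <- function() {
  tbl <- app_table()
  data.frame(
    id = vapply(tbl, `[[`, character(1L), "id"),
    title = vapply(tbl, `[[`, character(1L), "title"),
    description = vapply(tbl, `[[`, character(1L), "description"),
    backends = vapply(tbl, function(e) paste(e$backends, collapse = ","),
                      character(1L)),
    row.names = NULL)
}
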