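# Packaged fixtures: the expected coupling graphs of both architectures and
# reference numeric values, each carrying a provenance tag ("reported" for
# values taken from the behavioral/simulation report, "derived" for values
# implied by the architecture's function, "trivial" for bookkeeping).

fixture <- function(name, payload, citation) {
  structure(list(name = name, payload = payload, citation = citation),
            class = "dfwm_fixture")
}

#' Expected coupling graph of a model variant
#'
#' The adjacency table (source, target, sign) that [build_model1()] /
#' [build_model2()] must reproduce: the sensory-to-attention-to-working-
#' memory pathway with a shared inhibitory layer, plus (variant 2) the
#' spatial pathway, scene-level attention, and the peak-detector /
#' condition-of-satisfaction loop.
#'
#' @param variant 1 or 2.
#' @return data frame with columns source, target, sign.
#' @export
model_adjacency_fixture <- function(variant = 1) {
  core <- data.frame(
    source = c("CS", "CS", "CS", "FA", "FC", "FC", "FWM", "Inhib", "Inhib",
               "FWM", "FA"),
    target = c("FA", "FC", "FWM", "FC", "FWM", "Inhib", "Inhib", "FC", "FWM",
               "FA", "CS"),
    sign = c("excitatory", "excitatory", "excitatory", "excitatory",
             "excitatory", "excitatory", "excitatory", "inhibitory",
             "inhibitory", "excitatory", "excitatory"),
    citation = c(
      rep("[reported] architecture: sensory field feeds attention, contrast and (weakly) working memory", 3),
      "[reported] architecture: attention boosts the contrast field",
      "[reported] architecture: the contrast field is the primary input to working memory",
      "[reported] architecture: two excitatory fields reciprocally coupled to a single inhibitory field",
      "[reported] architecture: two excitatory fields reciprocally coupled to a single inhibitory field",
      "[reported] architecture: inhibitory feedback suppresses stored colors in the contrast field",
      "[reported] architecture: broad inhibition supports self-sustained peaks",
      "[derived] recall pathway: the cued working-memory peak must bias feature attention",
      "[reported] architecture: attention projects a ridge into the sensory field at recall"))
  if (variant == 1) return(core)
  extra <- data.frame(
    source = c("FC", "CS", "SA", "IOR", "SA", "FWM", "FA", "SLA", "SLA",
               "PD", "CoS", "CoS", "CoS", "CoS"),
    target = c("FA", "SA", "CS", "SA", "IOR", "SLA", "SLA", "FWM", "PD",
               "CoS", "FA", "SA", "SLA", "IOR"),
    sign = c("excitatory", "excitatory", "excitatory", "inhibitory",
             "excitatory", "excitatory", "excitatory", "excitatory",
             "excitatory", "excitatory", "inhibitory", "inhibitory",
             "inhibitory", "excitatory"),
    citation = c(
      "[reported] architecture: activation propagates first to the contrast field and then to feature attention",
      "[reported] architecture: spatial attention is driven through the sensory field",
      "[reported] architecture: biased competition via the sensory field",
      "[reported] architecture: inhibition-of-return suppresses re-selection of visited locations",
      "[derived] visited locations are stamped into the IOR field",
      "[reported] architecture: the consolidated peak drives scene-level attention",
      "[derived] conjunctive gating: only the currently attended and consolidated item forms a scene-level peak",
      "[reported] architecture: the spatial cue boost reaches working memory through scene-level attention",
      "[reported] architecture: the peak detector monitors scene-level attention",
      "[reported] architecture: the peak detector activates the condition-of-satisfaction node",
      rep("[reported] architecture: condition of satisfaction suppresses all three attention fields", 3),
      "[reported] architecture: condition of satisfaction boosts the IOR field"))
  rbind(core, extra)
}

#' All packaged numeric fixtures with their provenance tags
#'
#' Used by the fixture audit: every numeric value a test compares against
#' must carry a `[reported]`, `[derived]` or `[trivial]` tag.
#'
#' @return list of fixtures, each with name, payload and citation.
#' @export
packaged_fixtures <- function() {
  ref <- behavioral_reference()
  rmse <- reference_rmse_table()
  list(
    fixture("behavioral_reference", ref,
            paste0("[reported] ", paste(attr(ref, "citations"),
                                        collapse = " | "))),
    fixture("reference_rmse_table", rmse,
            paste("[reported] published RMSE rows: 1.77/6.91/0.07 (k = 49),",
                  "1.70/3.61/0.03 (k = 56), control 1.16/2.40/0.03;",
                  "published AIC values 131.96 and 132.01")),
    fixture("adjacency_model1", model_adjacency_fixture(1),
            "[reported] architecture diagram, variant 1 (see column `citation`)"),
    fixture("adjacency_model2", model_adjacency_fixture(2),
            "[reported] architecture diagram, variant 2 (see column `citation`)"),
    fixture("task_geometry",
            c(close_separation = 20, unique_distance = 170,
              min_location_gap = 80, n_wheel_colors = 180),
            paste("[reported] design: close hues 20 deg apart, unique hue 170",
                  "deg from each, locations at least 80 deg apart, 180 colors",
                  "in 2-deg steps")),
    fixture("session_composition",
            c(delay_ss1 = 160, delay_unique = 320, delay_cw = 160,
              delay_ccw = 160, control_unique = 320, control_cw = 160,
              control_ccw = 160),
            paste("[reported] design: 800 delay trials (160 set-size-1, 320",
                  "unique probes, 320 close probes) and 640 control trials",
                  "(320 unique, 160 CW, 160 CCW)"))
  )
}

#' Audit packaged fixtures for untagged numeric values
#'
#' @return `TRUE` invisibly if every fixture citation carries a provenance
#'   tag; otherwise the offending fixture names.
#' @export
audit_fixtures <- function() {
  bad <- character()
  for (f in packaged_fixtures()) {
    if (!grepl("\\[(reported|derived|trivial)\\]", f$citation))
      bad <- c(bad, f$name)
  }
  if (length(bad)) return(bad)
  invisible(TRUE)
}
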