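# Per-rule fixtures for the refinement catalogue: for every rule one text
# where it is the deciding rule (fire) and one close variant where it is not
# (nofire).  Shared by test-refinement.R and the acceptance suite.

rule_fixtures <- function() {
  f <- function(rule_id, fire, nofire, concept, fire_status) {
    data.frame(rule_id = rule_id, fire = fire, nofire = nofire,
               concept = concept, fire_status = fire_status,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("RET-01", "ZZZZZ restlessness has not worsened.",
      "He denies restlessness.", "restlessness", "positive"),
    f("RET-02", "There has been no increase in restlessness.",
      "There has been no mention of restlessness.", "restlessness",
      "positive"),
    f("RET-03", "His headache has not settled.",
      "His headache has not worsened.", "headache", "positive"),
    f("RET-04", "There is no improvement in nausea.",
      "There is no nausea.", "nausea", "positive"),
    f("RET-05", "Nausea is still not controlled.",
      "Nausea is not improving.", "nausea", "positive"),
    f("RET-06", "ZZZZZ disorientated and not taking his medication.",
      "ZZZZZ disorientated and not eating his meals.", "disorientation",
      "positive"),
    f("RET-07", "Restless and not compliant with his tablets.",
      "Restless and not engaging with staff.", "restlessness", "positive"),
    f("RET-08", "Dizzy and not taking the full dose.",
      "Dizzy and not taking the full course.", "dizziness", "positive"),
    f("RET-09", "Nauseous and not tolerating sertraline.",
      "Nauseous and not tolerating the situation.", "nausea", "positive"),
    f("REM-01", "Monitor for dizziness.",
      "Dizziness reported this morning.", "dizziness", "negative"),
    f("REM-02", "ZZZZZ was warned about dizziness.",
      "ZZZZZ was worried about dizziness.", "dizziness", "negative"),
    f("REM-03", "Olanzapine may cause weight gain.",
      "His weight gain continued.", "weight gain", "negative"),
    f("REM-04", "Myocarditis under investigation.",
      "Myocarditis confirmed on biopsy.", "myocarditis", "negative"),
    f("REM-05", "There is a risk of tachycardia.",
      "Tachycardia recorded overnight.", "tachycardia", "negative"),
    f("REM-06", "We discussed dizziness at the appointment.",
      "He mentioned dizziness at the appointment.", "dizziness", "negative"),
    f("REM-07", "Side effects include nausea.",
      "Nausea is one side effect.", "nausea", "negative"),
    f("REM-08", "Given a leaflet about dizziness.",
      "Given reassurance about dizziness.", "dizziness", "negative"),
    f("REM-09", "Unstable partial complex seizures.",
      "Frequent partial complex seizures.", "convulsions", "negative"),
    f("REM-10", "Query sedation.",
      "Marked sedation today.", "sedation", "negative"),
    f("REM-11", "Sedation? To be confirmed.",
      "Sedation confirmed.", "sedation", "negative"),
    f("REM-12", "Differential includes myocarditis.",
      "Myocarditis was confirmed today.", "myocarditis", "negative"),
    f("REM-13", "We cannot exclude myocarditis.",
      "We cannot overstate his myocarditis.", "myocarditis", "negative"),
    f("REM-14", "Dizziness *No * Yes.",
      "Dizziness No Yes.", "dizziness", "negative"),
    f("REM-15", "Dizziness Yes/No.",
      "Dizziness yes and no.", "dizziness", "negative"),
    f("REM-16", "I become restless x 5.",
      "I become restless at 5 pm.", "restlessness", "negative"),
    f("REM-17", "Constipation [ ] present.",
      "Constipation [severe] today.", "constipation", "negative"),
    f("REM-18", "Fainting/ dizziness on standing.",
      "Fainting and dizziness on standing.", "fainting", "negative"),
    f("REM-19", "Please circle dizziness if present.",
      "Please report dizziness to staff.", "dizziness", "negative"),
    f("REM-20", "Questionnaire covered anxiety today.",
      "Interview covered anxiety today.", "anxiety", "negative"),
    f("REM-21", "Email sjs@sydenham.lewisham.sch.uk please.",
      "SJS was raised at handover.", "sjs", "negative"),
    f("REM-22", "See www.nhs.uk/conditions/dizziness today.",
      "See the page about dizziness today.", "dizziness", "negative"),
    f("REM-23", "Seen at CENTRE FOR ANXIETY DISORDERS AND TRAUMA.",
      "Seen at the Centre for Anxiety Disorders.", "anxiety", "negative"),
    f("REM-24", "Referred to the clinic for anxiety management.",
      "The clinic reviewed his anxiety.", "anxiety", "negative"),
    f("REM-25", "Write to Anxiety House, London SE5 8AZ.",
      "Write to Anxiety House, London.", "anxiety", "negative"),
    f("REM-26", "Anxiety House sent a letter.",
      "Anxiety team meeting held.", "anxiety", "negative")
  )
}

# Deciding rule (refinement_rule) for the first mention of `concept`.
fired_rule_for <- function(text, concept) {
  ann <- annotate_document(text, lexicon = bundled_lexicon(),
                           rules = bundled_rules())
  row <- ann[ann$ade_type == concept, , drop = FALSE]
  if (nrow(row) == 0) return(list(rule = NA_character_,
                                  status = NA_character_))
  list(rule = row$refinement_rule[1], status = row$ade_status[1])
}
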