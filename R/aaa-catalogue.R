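# Shared entity/workflow catalogue used by the simulator and the QA engine.
# Tokens are generic: real datasets carry their own taxonomies, and the
# robot step / phase lists are configurable via sim_config().

.sterile_roles <- c("head_surgeon", "assistant_surgeon", "scrub_nurse")
.staff_roles <- c("assistant_surgeon", "scrub_nurse", "circulating_nurse",
                  "anaesthetist")
.person_classes <- c("head_surgeon", .staff_roles, "patient")
.furniture <- c("operating_table", "instrument_table", "anesthesia_machine",
                "tool_cart", "monitor")
.tools <- c("drill", "saw", "hammer", "scalpel")
.tool_colors <- c("blue", "green", "red", "black", "silver", "orange")
.phase_tools <- c(preparation = NA, incision = "scalpel", drilling = "drill",
                  sawing = "saw", implant_placement = "hammer", closing = NA)
.phase_verbs <- c(preparation = "preparing", incision = "cutting",
                  drilling = "drilling", sawing = "sawing",
                  implant_placement = "hammering", closing = "suturing")
.contact_predicates <- c("touching", "holding", "grasping")
.known_predicates <- c(.contact_predicates, "lying_on", "assisting",
                       "monitoring", "close_to", unname(.phase_verbs))
.phrasebook <- c("suction please", "handing over the drill",
                 "irrigation is running", "check the implant size",
                 "increase the table height", "next instrument please",
                 "the saw is ready", "hold the retractor steady",
                 "we are on the lateral side now", "prepare the cement",
                 "vitals are stable", "closing up shortly")
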