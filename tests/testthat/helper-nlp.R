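# crafted sentence fixtures covering presence, negation, removal, units,
# decimals and distractor tubes; the parser contract is 100% agreement
nlp_fixture <- function() {
  rbind(
    # --- presence, plain ---
    data.frame(text = "ET tube tip is 4.2 cm above the carina.",
               status = "PRESENT", dist = 4.2),
    data.frame(text = "Endotracheal tube in standard position.",
               status = "PRESENT", dist = NA),
    data.frame(text = "ETT tip terminates 3.0 cm above the carina.",
               status = "PRESENT", dist = 3.0),
    data.frame(text = "The endotracheal tube tip projects 5 cm above the carina.",
               status = "PRESENT", dist = 5),
    data.frame(text = "ETT is in satisfactory position.",
               status = "PRESENT", dist = NA),
    data.frame(text = "An ET tube is present.", status = "PRESENT", dist = NA),
    data.frame(text = "Endotracheal tube tip 2.8 cm from the carina.",
               status = "PRESENT", dist = 2.8),
    data.frame(text = "Interval placement of an endotracheal tube.",
               status = "PRESENT", dist = NA),
    data.frame(text = "ETT seen with tip at 6.1 cm above the carina.",
               status = "PRESENT", dist = 6.1),
    data.frame(text = "Support devices: ETT, right IJ central line.",
               status = "PRESENT", dist = NA),
    # --- millimetres and decimals ---
    data.frame(text = "ETT tip 35 mm above the carina.",
               status = "PRESENT", dist = 3.5),
    data.frame(text = "Endotracheal tube terminating 52 mm from the carina.",
               status = "PRESENT", dist = 5.2),
    data.frame(text = "ET tube tip 4.25 cm above the carina.",
               status = "PRESENT", dist = 4.25),
    data.frame(text = "ETT 0.9 cm above the carina; slightly low.",
               status = "PRESENT", dist = 0.9),
    data.frame(text = "ETT tip measured 19 mm above the carina, low position.",
               status = "PRESENT", dist = 1.9),
    # --- negation ---
    data.frame(text = "No endotracheal tube is seen.", status = "ABSENT", dist = NA),
    data.frame(text = "No ETT.", status = "ABSENT", dist = NA),
    data.frame(text = "There is no ET tube identified.", status = "ABSENT", dist = NA),
    data.frame(text = "Lines and tubes: none. No endotracheal tube present.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Patient without ETT on current exam.",
               status = "ABSENT", dist = NA),
    data.frame(text = "No evidence of ETT or central line.",
               status = "ABSENT", dist = NA),
    # --- removal / extubation ---
    data.frame(text = "The endotracheal tube has been removed.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Interval removal of the ET tube.", status = "ABSENT", dist = NA),
    data.frame(text = "Patient extubated; the ETT is no longer visualized.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Status post extubation, ETT withdrawn.",
               status = "ABSENT", dist = NA),
    data.frame(text = "ETT removed since the prior study.",
               status = "ABSENT", dist = NA),
    # --- no mention at all ---
    data.frame(text = "Clear lungs. No acute cardiopulmonary process.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Mild cardiomegaly, otherwise unremarkable.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Right basilar atelectasis.", status = "ABSENT", dist = NA),
    # --- distractor tubes must not trigger ---
    data.frame(text = "Nasogastric tube courses below the diaphragm.",
               status = "ABSENT", dist = NA),
    data.frame(text = "A chest tube is present on the left.",
               status = "ABSENT", dist = NA),
    data.frame(text = "NG tube tip in the stomach.", status = "ABSENT", dist = NA),
    data.frame(text = "Feeding tube terminates in the distal stomach.",
               status = "ABSENT", dist = NA),
    data.frame(text = "Tracheostomy tube is midline.", status = "ABSENT", dist = NA),
    # --- distractor + real ETT ---
    data.frame(text = "ETT tip 4.0 cm above the carina. Nasogastric tube in the stomach.",
               status = "PRESENT", dist = 4.0),
    data.frame(text = "NG tube and endotracheal tube both in standard position.",
               status = "PRESENT", dist = NA),
    # --- conflicts -> UNCERTAIN ---
    data.frame(text = "Lines and tubes unchanged. ETT in place. No ETT seen.",
               status = "UNCERTAIN", dist = NA),
    data.frame(text = "ET tube in good position. Addendum: no ET tube on repeat film.",
               status = "UNCERTAIN", dist = NA),
    # --- case-insensitivity ---
    data.frame(text = "ett tip is 3.9 cm above the carina.",
               status = "PRESENT", dist = 3.9),
    data.frame(text = "ENDOTRACHEAL TUBE TIP 45 MM ABOVE THE CARINA.",
               status = "PRESENT", dist = 4.5),
    # --- distance phrasing that must NOT parse a number ---
    data.frame(text = "ETT tip at the carina.", status = "PRESENT", dist = NA),
    data.frame(text = "Endotracheal tube tip several centimeters above the carina.",
               status = "PRESENT", dist = NA))
}
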