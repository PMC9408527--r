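#semantic=non-physician personnel,syntactic=noun
nurse, nurses, receptionist, receptionists, assistant, assistants, staff,
paramedic, paramedics, pharmacist, pharmacists, lady, technician, technicians
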