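code_key,description,allocation,work_rvu,billing,payable_commercial,payable_medicare,payable_medicaid
office_visit,Physician office visit,1.00000000000000000,1.92000000000000015,per_visit,payable,payable,payable
hba1c_test,Hemoglobin A1c level,1.00000000000000000,,per_visit,payable,payable,payable
urinalysis,Urinalysis,1.00000000000000000,,per_visit,bundled,bundled,bundled
lipid_panel,Lipid panel,0.44000000000000000,,per_visit,payable,payable,payable
cbc_auto_diff,Complete blood count with auto-differential,1.00000000000000000,,per_visit,payable,payable,payable
bp_setup_education,Education on self-managed blood pressure setup,0.68000000000000005,0.17994694960212201,per_visit,payable,payable,payable
bp_monitor_education,Education on self-managed blood pressure monitor,0.68000000000000005,0.23992705570291778,per_visit,payable,payable,not_covered
tobacco_cessation,Tobacco cessation,0.22000000000000000,0.23987704918032787,per_visit,payable,payable,payable
foot_exam,Diabetic foot examination,1.00000000000000000,,per_visit,bundled,bundled,bundled
depression_screen,Depression screening,0.25000000000000000,,per_visit,payable,payable,payable
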