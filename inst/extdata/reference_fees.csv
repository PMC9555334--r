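payer,code_key,fee_usd
commercial,office_visit,147.4187122945704118
commercial,hba1c_test,19.3228884959434168
commercial,lipid_panel,26.6471040189125290
commercial,cbc_auto_diff,7.7311472852090697
commercial,bp_setup_education,3.5390027531355153
commercial,bp_monitor_education,60.6132609360660766
commercial,tobacco_cessation,10.3893617021276601
commercial,depression_screen,6.2764143094841929
medicare,office_visit,103.0899764547595083
medicare,hba1c_test,9.7099730911537172
medicare,lipid_panel,13.3912461773700304
medicare,cbc_auto_diff,3.8849646821392532
medicare,bp_setup_education,2.4745301681503462
medicare,bp_monitor_education,42.3824183976261111
medicare,tobacco_cessation,7.2656727828746179
medicare,depression_screen,4.3913189771197843
medicaid,office_visit,66.1400208986415947
medicaid,hba1c_test,8.9899425287356323
medicaid,lipid_panel,12.4023159144893107
medicaid,cbc_auto_diff,3.5949582027168234
medicaid,bp_setup_education,2.0568356374807988
medicaid,tobacco_cessation,4.7161520190023749
medicaid,depression_screen,3.9660751565762005
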