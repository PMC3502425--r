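du_as_long_as_needed	du	10	as long as needed[.,]?
du_xdays	du	10	x[0-9]+ (days?|weeks?|months?)[.,]?
du_for_n_units	du	10	for (a|one|two|three|four|five|six|seven|eight|nine|ten|[0-9]+) (days?|weeks?|months?)[.,]?
du_n_day_course	du	10	[0-9]+-day course[.,]?
du_during	du	12	during (spring|winter|summer|fall) break[.,]?
f_q_n_prn	f	20	q [0-9]+ prn[.,]?
f_q_n_hours	f	20	q[.]? [0-9]+(-[0-9]+)? (h|hr|hrs|hours?)[.,]?
f_n_times_a_day	f	20	(once|twice|three|four) times a (day|week|month)[.,]?
f_once_a_day	f	22	(once|twice) (a|per) (day|week|month)[.,]?
f_every_n	f	22	every ([0-9]+|other) (hours?|days?|day|night|morning|evening)[.,]?
f_abbrev	f	25	(qd|bid|tid|qid|qhs|qam|qpm|q[.]d[.]?|b[.]i[.]d[.]?|t[.]i[.]d[.]?|q[.]h[.]s[.]?)[.,]?
f_before_meal	f	25	x[0-9]+ (before|after) (meal|meals)[.,]?
f_daily	f	28	(daily|nightly|weekly|monthly)[.,]?
f_at_bedtime	f	28	at (bedtime|night)[.,]?
f_as_needed	f	30	as needed[.,]?
f_prn	f	35	prn[.,]?
do_n_unit	do	40	[0-9]+([.,][0-9]+)?(-[0-9]+([.,][0-9]+)?)? (mg|mcg|g|gm|ml|cc|meq|units?|tabs?|tablets?|capsules?|caps?|puffs?|drops?|sprays?|patch(es)?)[.,]?
do_word_unit	do	40	(one|two|three|four|half) (tab|tabs|tablet|tablets|capsules?|puffs?|drops?)[.,]?
do_attached_unit	do	42	[0-9]+([.][0-9]+)?(mg|mcg|ml|g|meq|units?)[.,]?
do_percent_form	do	42	[0-9]+([.][0-9]+)?% (cream|ointment|solution|gel|lotion)[.,]?
do_n_mg_x_n	do	38	[0-9]+([.][0-9]+)? (mg|mcg|g) x [0-9]+ (tablets?|tabs?|capsules?)[.,]?
mo_po	mo	50	p[.]o[.]?[.,]?
mo_iv_abbrev	mo	50	(iv|i[.]v[.]?|im|i[.]m[.]?|sq|s[.]q[.]?|sc|s[.]c[.]?)[.,]?
mo_word	mo	50	(orally|intravenous(ly)?|topical(ly)?|sublingual(ly)?|subcutaneous(ly)?|intramuscular(ly)?|inhaled|nebulized|transdermal(ly)?)[.,]?
mo_by_mouth	mo	50	by mouth[.,]?
mo_via	mo	52	via (nebulizer|inhaler)[.,]?
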