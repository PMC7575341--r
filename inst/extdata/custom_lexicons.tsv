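category	entry
suicidality	suicid*
suicidality	kill_myself
suicidality	end_my_life
suicidality	want_to_die
suicidality	self_harm
suicidality	overdose
suicidality	hopeless
suicidality	worthless
suicidality	no_reason_to_live
economic_stress	rent
economic_stress	debt*
economic_stress	unemploy*
economic_stress	layoff*
economic_stress	laid_off
economic_stress	evict*
economic_stress	bills
economic_stress	pay_the_bills
economic_stress	paycheck
economic_stress	broke
economic_stress	afford*
isolation	lonely
isolation	loneliness
isolation	alone
isolation	isolat*
isolation	quarantine
isolation	lockdown
isolation	can't_see_anyone
isolation	stuck_inside
isolation	no_one_to_talk
substance_use	drunk
substance_use	alcohol*
substance_use	drug*
substance_use	weed
substance_use	high
substance_use	relapse*
substance_use	sober
substance_use	withdraw*
substance_use	addict*
substance_use	overdose
domestic_stress	argument*
domestic_stress	fighting
domestic_stress	yelling
domestic_stress	divorce*
domestic_stress	abus*
domestic_stress	custody
domestic_stress	screaming
domestic_stress	violent
domestic_stress	shouting
guns	gun*
guns	rifle*
guns	pistol
guns	firearm*
guns	ammo
guns	ammunition
guns	bullet*
guns	shoot*
guns	trigger
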