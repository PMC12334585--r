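category_id,activity_type
community,Community
entertainment,Entertainment
food,Food
nightlife,Entertainment
outdoors,Outdoors
shopping,Shopping
travel,Travel
home,Residence
apartment,Residence
condo,Residence
dormitory,Residence
residence_other,Residence
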